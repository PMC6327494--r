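# Trail grouping: reaction sets, neighbor rule, and the two conservation
# tables on the two-genome worked example.

test_that("trails reduce to reaction sets regardless of order/repeats", {
  expect_equal(reaction_set(c("r2", "r7", "r8", "r3", "r4")),
               c("r2", "r3", "r4", "r7", "r8"))
  expect_equal(reaction_set(c("r2", "r3", "r7", "r8", "r3", "r4")),
               c("r2", "r3", "r4", "r7", "r8"))
  expect_identical(reaction_set(c("r9", "r10")),
                   reaction_set(c("r10", "r9")))
  expect_error(reaction_set(character(0)), "empty")
})

test_that("pooling merges duplicate sets across gap settings", {
  recs <- data.frame(
    species = "S", pathway = "p", delta_d = c(0L, 1L, 0L),
    delta_g = c(0L, 2L, 0L),
    reactions = c("r1;r2", "r2;r1;r2", "r3;r4"),
    span = c(2L, 2L, 2L), genes = "", stringsAsFactors = FALSE)
  pool <- pool_reaction_sets(recs)
  expect_length(pool, 2L)
  expect_equal(names(pool), c("r1;r2", "r3;r4"))
  expect_length(pool_reaction_sets(recs[0, ]), 0L)
})

test_that("the neighbor rule skips up to the gap and demands one strand", {
  fx <- table1_instance()
  g1 <- fx$genomes$S1
  expect_true(genes_neighboring(g1, c("T1", "W1", "X1")))
  expect_false(genes_neighboring(g1, c("A1", "W1")))
  expect_true(genes_neighboring(g1, "A1"))
  expect_error(genes_neighboring(g1, "nope"), "unknown gene")
  mixed <- genome_table("m", data.frame(
    gene_id = c("p1", "p2", "m1"), chromosome = "chr",
    strand = c("+", "+", "-"), position = c(0L, 1L, 0L),
    stringsAsFactors = FALSE))
  expect_false(genes_neighboring(mixed, c("p1", "m1")))
})

test_that("the largest neighbored subset matches the worked example", {
  fx <- table1_instance()
  sub <- neighbored_reaction_subset(c("r2", "r3", "r6", "r7", "r8"),
                                    fx$genomes$S1, fx$correspondences$S1)
  expect_equal(as.character(sub), c("r6", "r7", "r8"))
  expect_equal(attr(sub, "genes"), c("T1", "W1", "X1"))
  # species performing none of the set
  none <- neighbored_reaction_subset(c("zz1", "zz2"), fx$genomes$S1,
                                     fx$correspondences$S1)
  expect_length(none, 0L)
  # the reference against itself recovers the full set
  own <- neighbored_reaction_subset(c("r2", "r3", "r6", "r7", "r8"),
                                    fx$genomes$S, fx$correspondences$S)
  expect_equal(as.character(own), c("r2", "r3", "r6", "r7", "r8"))
})

test_that("by-reactions table reproduces the worked-example column", {
  fx <- table1_instance()
  panel <- panel_config("S", "S1")
  tbl <- group_by_reactions(panel, table1_pooled(fx))
  expect_equal(tbl$rows$reaction, c("r2", "r8", "r3", "r7", "r6"))
  expect_equal(unname(tbl$cells[, "S1"]), c(".", "x", "", "x", "x"))
  # cross implies performed; blank implies not performed
  for (i in seq_len(nrow(tbl$rows))) {
    performed <- length(corr_genes(fx$correspondences$S1,
                                   tbl$rows$reaction[[i]])) > 0L
    if (tbl$cells[i, "S1"] == "x") expect_true(performed)
    if (tbl$cells[i, "S1"] == "") expect_false(performed)
  }
})

test_that("by-genes table reproduces the worked-example column", {
  fx <- table1_instance()
  panel <- panel_config("S", "S1")
  tbl <- group_by_genes(panel, table1_pooled(fx))
  expect_equal(tbl$rows$gene_id, c("U", "X", "V", "W", "T"))
  expect_equal(unname(tbl$cells[, "S1"]), c(".", "x", ".", "x", "x"))
  det <- tbl$details[[paste(1L, "S1", sep = "\r")]]
  expect_equal(det$h_prime, c("T1", "W1", "X1"))
  expect_equal(det$g_prime, c("T", "W", "X"))
  # crosses in the column equal |G'| of the group
  expect_equal(sum(tbl$cells[, "S1"] == "x"), length(det$g_prime))
})

test_that("by-genes dots are ambiguous where by-reactions distinguishes", {
  fx <- table1_instance()
  panel <- panel_config("S", "S1")
  pooled <- table1_pooled(fx)
  tg <- group_by_genes(panel, pooled)
  tr <- group_by_reactions(panel, pooled)
  # genes U (reaction r2, performed afar) and V (r3, absent) both dot ...
  expect_equal(unname(tg$cells[tg$rows$gene_id %in% c("U", "V"), "S1"]),
               c(".", "."))
  # ... while the reaction table separates them: r2 dot, r3 blank
  expect_equal(unname(tr$cells[tr$rows$reaction == "r2", "S1"]), ".")
  expect_equal(unname(tr$cells[tr$rows$reaction == "r3", "S1"]), "")
})

test_that("genes outside shared reaction sets are excluded from rows", {
  fx <- table1_instance()
  pooled <- table1_pooled(fx)
  # add a reference-only reaction set backed by a new gene
  g2 <- genome_table("S", data.frame(
    gene_id = c("U", "X", "V", "W", "T", "Z"), chromosome = "chr",
    strand = "+", position = 0:5, stringsAsFactors = FALSE))
  corr2 <- correspondence(list(r2 = "U", r8 = "X", r3 = "V", r7 = "W",
                               r6 = "T", r99 = "Z"), g2)
  recs <- rbind(fx$records$S,
                within(fx$records$S, reactions <- "r99"))
  pooled$S <- species_data(g2, corr2, recs)
  tbl <- group_by_genes(panel_config("S", "S1"), pooled)
  expect_false("Z" %in% tbl$rows$gene_id)
})

test_that("grouping is invariant to record order", {
  fx <- table1_instance()
  pooled <- table1_pooled(fx)
  recs <- rbind(fx$records$S, fx$records$S,
                within(fx$records$S, reactions <- "r8;r3;r7;r8;r2;r3"))
  pooled_a <- pooled
  pooled_a$S <- species_data(fx$genomes$S, fx$correspondences$S, recs)
  pooled_b <- pooled
  pooled_b$S <- species_data(fx$genomes$S, fx$correspondences$S,
                             recs[rev(seq_len(nrow(recs))), ])
  ta <- group_by_reactions(panel_config("S", "S1"), pooled_a)
  tb <- group_by_reactions(panel_config("S", "S1"), pooled_b)
  expect_identical(ta$rows, tb$rows)
  expect_identical(ta$cells, tb$cells)
})

test_that("grouping CSVs round trip their symbols", {
  fx <- table1_instance()
  panel <- panel_config("S", "S1")
  pooled <- table1_pooled(fx)
  tr <- group_by_reactions(panel, pooled)
  f <- tempfile(fileext = ".csv")
  write_grouping_csv(tr, f)
  back <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
  expect_equal(nrow(back), 5L)
  expect_equal(back$S1, c(".", "x", "", "x", "x"))
  tg <- group_by_genes(panel, pooled)
  f2 <- tempfile(fileext = ".csv")
  write_grouping_csv(tg, f2)
  back2 <- utils::read.csv(f2, colClasses = "character",
                           check.names = FALSE)
  expect_equal(back2$gene, c("U", "X", "V", "W", "T"))
  expect_equal(back2$S1, c(".", "x", ".", "x", "x"))
  # empty table: header-only CSV
  empty <- group_by_reactions(panel, within(pooled, S <- species_data(
    fx$genomes$S, fx$correspondences$S, NULL)))
  f3 <- tempfile(fileext = ".csv")
  write_grouping_csv(empty, f3)
  expect_equal(nrow(utils::read.csv(f3, check.names = FALSE)), 0L)
})

test_that("panel configuration rejects degenerate panels", {
  expect_error(panel_config("S", character(0)), "at least one")
  expect_error(panel_config("S", c("S", "S1")), "must not appear")
  expect_error(group_by_reactions(panel_config("S", "S9"),
                                  table1_pooled()), "S9")
})
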