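# Core model: graph containers, gene neighborhood, reaction adjacency,
# gap expansion, trails and span.

test_that("pathway_graph normalises to a simple digraph", {
  D <- pathway_graph(rbind(c("b", "a"), c("b", "a"), c("a", "a"),
                           c("a", "b")),
                     vertices = "z")
  expect_equal(D$vertices, c("a", "b", "z"))
  expect_equal(n_arcs(D), 2L)
  expect_true(has_arc(D, c("a", "b")))
  expect_false(has_arc(D, c("a", "z")))
  expect_error(pathway_graph(rbind(c("", "b"))), "non-empty")
})

test_that("gene graph links same-strand genes within the gap", {
  g <- genome_table("sp", data.frame(
    gene_id = paste0("g", 0:5), chromosome = "chr", strand = "+",
    position = 0:5, stringsAsFactors = FALSE))
  gg0 <- build_gene_graph(g, 0L)
  # strict adjacency only
  expect_true(any(gg0$edges[, 1L] == "g3" & gg0$edges[, 2L] == "g4"))
  expect_equal(nrow(gg0$edges), 5L)
  # positions 0 and 5 have four genes between: not linked at gap 3
  gg3 <- build_gene_graph(g, 3L)
  expect_false(any(gg3$edges[, 1L] == "g0" & gg3$edges[, 2L] == "g5"))
  expect_true(any(gg3$edges[, 1L] == "g0" & gg3$edges[, 2L] == "g4"))
  expect_error(build_gene_graph(g, -1), "non-negative")
})

test_that("murD and murG become neighbors when one gene may be skipped", {
  gg1 <- build_gene_graph(mur_genome(), 1L)
  expect_true(any(gg1$edges[, 1L] == "b0088" & gg1$edges[, 2L] == "b0090"))
  gg0 <- build_gene_graph(mur_genome(), 0L)
  expect_false(any(gg0$edges[, 1L] == "b0088" & gg0$edges[, 2L] == "b0090"))
})

test_that("gene-graph edges never join strands or chromosomes", {
  for (seed in 1:8) {
    inst <- random_instance(seed, n_genes = 12L, delta_g = seed %% 4L)
    genes <- inst$genome$genes
    gg <- inst$gene_graph
    if (nrow(gg$edges) == 0L) next
    for (i in seq_len(nrow(gg$edges))) {
      a <- genes[genes$gene_id == gg$edges[i, 1L], ]
      b <- genes[genes$gene_id == gg$edges[i, 2L], ]
      expect_identical(a$chromosome, b$chromosome)
      expect_identical(a$strand, b$strand)
    }
  }
})

test_that("circular chromosomes wrap the neighborhood", {
  g <- genome_table("sp", data.frame(
    gene_id = paste0("g", 0:5), chromosome = "chr", strand = "+",
    position = 0:5, stringsAsFactors = FALSE), circular = TRUE)
  gg0 <- build_gene_graph(g, 0L)
  expect_true(any(gg0$edges[, 1L] == "g0" & gg0$edges[, 2L] == "g5"))
  lin <- genome_table("sp", g$genes, circular = FALSE)
  expect_false(any(build_gene_graph(lin, 0L)$edges[, 1L] == "g0" &
                   build_gene_graph(lin, 0L)$edges[, 2L] == "g5"))
})

test_that("reaction adjacency lifts gene adjacency and shared genes", {
  genome <- genome_table("sp", data.frame(
    gene_id = c("X", "Y"), chromosome = "chr", strand = "+",
    position = 0:1, stringsAsFactors = FALSE))
  corr <- correspondence(list(r8 = "X", r9 = "Y", r10 = "Y"), genome)
  D <- pathway_graph(rbind(c("r8", "r9"), c("r9", "r10")),
                     vertices = "r99")
  G <- build_reaction_adjacency(D, build_gene_graph(genome, 0L), corr)
  expect_setequal(G$vertices, D$vertices)
  has_edge <- function(a, b) {
    e <- sort(c(a, b), method = "radix")
    any(G$edges[, 1L] == e[1L] & G$edges[, 2L] == e[2L])
  }
  expect_true(has_edge("r8", "r9"))
  expect_true(has_edge("r8", "r10"))
  # shared-gene rule: r9 and r10 are both catalyzed by Y
  expect_true(has_edge("r9", "r10"))
  # unmapped reaction stays isolated
  expect_false(any(G$edges == "r99"))
})

test_that("shared-gene adjacency matches brute-force construction", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n_reactions = 5L, n_genes = 7L,
                            gene_reaction_rate = 0.4)
    G <- inst$G
    adj <- trailspan:::und_adjacency(inst$gene_graph)
    verts <- inst$D$vertices
    for (i in seq_along(verts)) {
      for (j in seq_along(verts)) {
        if (i >= j) next
        gi <- corr_genes(inst$correspondence, verts[[i]])
        gj <- corr_genes(inst$correspondence, verts[[j]])
        expected <- FALSE
        for (a in gi) for (b in gj) {
          if (a == b || b %in% adj[[a]]) expected <- TRUE
        }
        e <- sort(c(verts[[i]], verts[[j]]), method = "radix")
        got <- any(G$edges[, 1L] == e[1L] & G$edges[, 2L] == e[2L])
        expect_identical(got, expected)
      }
    }
  }
})

test_that("gap expansion follows directed paths with bounded skips", {
  chain <- pathway_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  e0 <- expand_gaps_directed(chain, 0L)
  expect_identical(e0$arcs, chain$arcs)
  e1 <- expand_gaps_directed(chain, 1L)
  expect_true(has_arc(e1, c("a", "c")))
  expect_true(has_arc(e1, c("b", "d")))
  expect_false(has_arc(e1, c("a", "d")))
  expect_false(has_arc(e1, c("c", "a")))
  expect_error(expand_gaps_directed(chain, -2), "non-negative")
})

test_that("gap expansion is monotone in delta_d", {
  for (seed in 1:6) {
    inst <- random_instance(seed, n_reactions = 7L, arc_density = 0.25)
    prev <- character(0)
    for (dd in 0:3) {
      ex <- expand_gaps_directed(inst$D_raw, dd)
      cur <- paste(ex$arcs[, 1L], ex$arcs[, 2L])
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("span counts distinct reactions", {
  expect_equal(trail_span(trail(c("r2", "r3", "r7", "r8", "r3", "r4"))), 5L)
  expect_equal(trail_span(trail()), 0L)
  expect_equal(trail_span(c("r5", "r6", "r2", "r3", "r7", "r8", "r3",
                            "r4", "r9", "r10")), 9L)
})

test_that("trail validation enforces arcs and arc-distinctness", {
  fx <- fig1_instance()
  expect_silent(trail(c("r3", "r7", "r8", "r3", "r4"), D = fx$D))
  expect_error(trail(c("r1", "r3"), D = fx$D), "not arcs")
  expect_error(trail(c("r1", "r2", "r1"), D = fx$D), "not arcs")
  expect_error(trail(c("r7", "r8", "r3", "r7", "r8"), D = fx$D),
               "repeats an arc")
})

test_that("genome tables reject malformed input", {
  expect_error(genome_table("sp", data.frame(
    gene_id = c("a", "b"), chromosome = "c", strand = "+",
    position = c(0L, 2L))), "consecutive ordinals")
  expect_error(genome_table("sp", data.frame(
    gene_id = c("a", "b"), chromosome = "c", strand = c("+", "?"),
    position = c(0L, 0L))), "strand")
  expect_error(correspondence(list(r1 = "nope"),
                              genome_table("sp", data.frame(
                                gene_id = "a", chromosome = "c",
                                strand = "+", position = 0L))),
               "unknown genes")
})
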