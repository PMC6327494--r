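# The exact solver: reduction, support, consistency, per-arc solving.

test_that("graph reduction preserves the worked example unchanged", {
  fx <- fig1_instance()
  red <- graph_reduction(fx$D, fx$G, c("r1", "r2"))
  expect_identical(red$D$arcs, fx$D$arcs)
  expect_setequal(red$D$vertices, fx$D$vertices)
  expect_error(graph_reduction(fx$D, fx$G, c("r1", "r9")), "not an arc")
})

test_that("graph reduction removes foreign weak components", {
  D <- pathway_graph(rbind(c("a", "b"), c("x", "y")))
  G <- complete_und_graph(D$vertices)
  red <- graph_reduction(D, G, c("a", "b"))
  expect_setequal(red$D$vertices, c("a", "b"))
  expect_false("x" %in% red$G$vertices)
})

test_that("solver returns the attested spans on the worked example", {
  fx <- fig1_instance()
  s <- max_span_trail(fx$D, fx$G, c("r1", "r2"))
  expect_equal(s$span, 8L)
  expect_equal(s$through_arc, c("r1", "r2"))
  expect_equal(trail_span(s$trail), s$span)
  expect_true(is_supported(s$trail, fx$G))
  expect_equal(max_span_trail(fx$D, fx$G, c("r2", "r7"))$span, 9L)
})

test_that("single supported arc yields the two-reaction trail", {
  D <- pathway_graph(rbind(c("a", "b")))
  G <- und_graph(c("a", "b"), rbind(c("a", "b")))
  s <- max_span_trail(D, G, c("a", "b"))
  expect_equal(s$trail$reactions, c("a", "b"))
  expect_equal(s$span, 2L)
})

test_that("unsupportable arcs give an empty solution", {
  # no G edge anywhere: no supported trail of length >= 1 exists
  D <- pathway_graph(rbind(c("a", "b"), c("b", "c")))
  G <- und_graph(D$vertices)
  s <- max_span_trail(D, G, c("a", "b"))
  expect_null(s$trail)
  expect_equal(s$span, 0L)
})

test_that("support demands induced connectivity in G", {
  fx <- fig1_instance()
  expect_true(is_supported(trail("r1"), fx$G))
  G2 <- und_graph(c("a", "b", "c"), rbind(c("a", "b")))
  expect_false(is_supported(c("a", "c"), G2))
  expect_true(is_supported(c("a", "b"), G2))
  p2 <- trail_from_line_path(rbind(c("r5", "r6"), c("r6", "r2"),
                                   c("r2", "r7"), c("r7", "r8"),
                                   c("r8", "r3"), c("r3", "r4"),
                                   c("r4", "r9"), c("r9", "r10")))
  expect_true(is_supported(p2, fx$G))
})

test_that("genomic consistency accepts the mur-style neighborhood", {
  genome <- mur_genome()
  corr <- mur_correspondence(genome)
  gg1 <- build_gene_graph(genome, 1L)
  t_mur <- c("Ra", "Rb", "Rc", "Rd", "Re", "Rf")
  ok <- genomic_consistency(t_mur, gg1, corr)
  expect_true(c(ok))
  expect_setequal(attr(ok, "genes"),
                  c("b0085", "b0086", "b0087", "b0088", "b0090", "b0091"))
  # at gap 0 the non-enzyme gene b0089 breaks the chain
  gg0 <- build_gene_graph(genome, 0L)
  expect_false(isTRUE(c(genomic_consistency(t_mur, gg0, corr))))
  # single reaction with a gene anchors trivially
  expect_true(c(genomic_consistency("Ra", gg0, corr)))
  # reaction with no mapped gene cannot anchor
  expect_false(isTRUE(c(genomic_consistency(c("Ra", "Rzz"), gg1, corr))))
})

test_that("genomic consistency fails across chromosomes", {
  genome <- genome_table("sp", data.frame(
    gene_id = c("a1", "b1"), chromosome = c("c1", "c2"), strand = "+",
    position = c(0L, 0L), stringsAsFactors = FALSE))
  corr <- correspondence(list(R1 = "a1", R2 = "b1"), genome)
  gg <- build_gene_graph(genome, 3L)
  expect_false(isTRUE(c(genomic_consistency(c("R1", "R2"), gg, corr))))
})

test_that("solve_pathway reports maximal consistent trails once", {
  fx <- fig1_instance()
  # genome in which all ten reactions map to ten consecutive genes
  genome <- genome_table("sp", data.frame(
    gene_id = sprintf("g%02d", 1:10), chromosome = "chr", strand = "+",
    position = 0:9, stringsAsFactors = FALSE))
  mapping <- stats::setNames(as.list(sprintf("g%02d", 1:10)),
                             sprintf("r%d", 1:10))
  corr <- correspondence(mapping, genome)
  gg <- build_gene_graph(genome, 3L)
  res <- solve_pathway(fx$D, fx$G, gg, corr, species = "sp",
                       pathway = "toy00001")
  expect_false(res$timed_out)
  expect_true(any(res$records$span == 9L))
  expect_true(all(res$records$span <= 9L))
  expect_false(anyDuplicated(res$records$reactions) > 0L)
  # no reported trail is a contiguous sub-trail of another
  seqs <- strsplit(res$records$reactions, ";", fixed = TRUE)
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i == j) next
      expect_false(trailspan:::is_contiguous_subtrail(seqs[[i]],
                                                      seqs[[j]]))
    }
  }
})

test_that("solve_pathway handles empty and unsupported pathways", {
  empty <- solve_pathway(pathway_graph(), und_graph(), und_graph(),
                         correspondence())
  expect_equal(nrow(empty$records), 0L)
  D <- pathway_graph(rbind(c("a", "b")))
  G <- und_graph(D$vertices)  # no edges: nothing supported
  genome <- genome_table("sp", data.frame(
    gene_id = "g1", chromosome = "chr", strand = "+", position = 0L))
  res <- solve_pathway(D, G, build_gene_graph(genome, 0L),
                       correspondence(list(a = "g1", b = "g1"), genome))
  expect_equal(nrow(res$records), 0L)
})

test_that("a too-small budget flags the pathway for the blacklist", {
  fx <- fig1_instance()
  genome <- genome_table("sp", data.frame(
    gene_id = "g1", chromosome = "chr", strand = "+", position = 0L))
  corr <- correspondence(stats::setNames(rep(list("g1"), 10),
                                         sprintf("r%d", 1:10)), genome)
  res <- solve_pathway(fx$D, fx$G, build_gene_graph(genome, 0L), corr,
                       timeout = 1e-6)
  expect_true(res$timed_out)
  expect_true(res$blacklist)
  expect_equal(nrow(res$records), 0L)
})
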