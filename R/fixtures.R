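# Deterministic worked-example instances, seeded random instances, and an
# exhaustive brute-force oracle for the maximum-span supported trail
# problem. The oracle is written against its own minimal graph routines so
# it stays independent of the solver machinery it is used to check.

#' Worked-example pathway instance
#'
#' The ten-reaction pathway used throughout the documentation: reactions
#' r1..r10 with twelve arcs forming a central cycle r2-r3-r4-r5-r6 plus the
#' detour r3/r2-r7-r8-r3, source r1 and sink branch r4-r9-r10. The
#' companion undirected graph is complete, so connectivity never
#' constrains; the maximum spans through (r1,r2) and (r2,r7) are 8 and 9.
#'
#' @return List with components `D` (a [pathway_graph()]) and `G`
#'   (a complete [und_graph()] on the same vertices).
#' @export
fig1_instance <- function() {
  arcs <- rbind(c("r1", "r2"), c("r2", "r3"), c("r2", "r7"), c("r3", "r4"),
                c("r3", "r7"), c("r4", "r5"), c("r4", "r9"), c("r5", "r6"),
                c("r6", "r2"), c("r7", "r8"), c("r8", "r3"), c("r9", "r10"))
  D <- pathway_graph(arcs)
  list(D = D, G = complete_und_graph(D$vertices))
}

#' Two-genome grouping instance
#'
#' Didactic two-species instance for the grouping tables. The reference
#' species S carries the consecutive genes U, X, V, W, T (positions 0..4,
#' plus strand) catalyzing r2, r8, r3, r7, r6. Species S1 carries A1
#' (catalyzing r2) followed by four filler genes, then X1 (r8), the
#' non-enzyme gene B1, W1 (r7) and T1 (r6); S1 does not perform r3. Thus
#' T1, W1, X1 are neighboring (B1 is skipped) while A1 is too distant.
#' Both species contribute the reaction set \{r2, r3, r6, r7, r8\} to the
#' trail pool, so that the set counts as shared and the by-genes table has
#' rows; the pattern stands for the cross-species trail under study rather
#' than for a solver run on S1.
#'
#' @return List with `reference`, `species`, `genomes`, `correspondences`
#'   and `records` (per-species trail-record data frames).
#' @export
table1_instance <- function() {
  genome_s <- genome_table("S", data.frame(
    gene_id = c("U", "X", "V", "W", "T"),
    chromosome = "chr", strand = "+", position = 0:4,
    stringsAsFactors = FALSE))
  corr_s <- correspondence(list(r2 = "U", r8 = "X", r3 = "V", r7 = "W",
                                r6 = "T"), genome_s)
  genome_s1 <- genome_table("S1", data.frame(
    gene_id = c("A1", "F1", "F2", "F3", "F4", "X1", "B1", "W1", "T1"),
    chromosome = "chr", strand = "+", position = 0:8,
    stringsAsFactors = FALSE))
  corr_s1 <- correspondence(list(r2 = "A1", r8 = "X1", r7 = "W1",
                                 r6 = "T1"), genome_s1)
  rec <- function(sp, reactions) {
    data.frame(species = sp, pathway = "toy00001", delta_d = 0L,
               delta_g = 0L, reactions = reactions,
               span = length(strsplit(reactions, ";")[[1L]]),
               genes = "", stringsAsFactors = FALSE)
  }
  list(reference = "S", species = "S1",
       genomes = list(S = genome_s, S1 = genome_s1),
       correspondences = list(S = corr_s, S1 = corr_s1),
       records = list(S = rec("S", "r6;r2;r3;r7;r8"),
                      S1 = rec("S1", "r2;r3;r6;r7;r8")))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Seeded random instance
#'
#' Generates a reproducible random pathway/genome instance: a simple
#' directed reaction graph with the requested arc density, a one-chromosome
#' genome with genes assigned randomly to the two strands, and a random
#' reaction-gene correspondence. The gene-neighborhood graph and the
#' derived reaction-adjacency graph are built through the standard model
#' operations at the given gap parameters.
#'
#' @param seed integer seed; identical seeds give identical instances.
#' @param n_reactions number of reactions (>= 1).
#' @param arc_density probability of each ordered reaction pair being an
#'   arc, in `[0, 1]`.
#' @param n_genes number of genes (>= 1).
#' @param gene_reaction_rate probability that a given gene catalyzes a
#'   given reaction, in `[0, 1]`.
#' @param delta_d,delta_g gap parameters applied while deriving the
#'   expanded pathway graph and the gene graph.
#' @return List with `seed`, `D` (gap-expanded), `D_raw`, `G`, `genome`,
#'   `correspondence` and `gene_graph`.
#' @export
random_instance <- function(seed, n_reactions = 6L, arc_density = 0.3,
                            n_genes = 8L, gene_reaction_rate = 0.3,
                            delta_d = 0L, delta_g = 0L) {
  if (n_reactions < 1L || n_genes < 1L)
    stop("sizes must be at least 1")
  if (arc_density < 0 || arc_density > 1 ||
      gene_reaction_rate < 0 || gene_reaction_rate > 1)
    stop("densities must lie in [0, 1]")
  with_seed(seed, {
    rxns <- sprintf("R%02d", seq_len(n_reactions))
    pairs <- expand.grid(from = rxns, to = rxns, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    keep <- stats::runif(nrow(pairs)) < arc_density
    D_raw <- pathway_graph(as.matrix(pairs[keep, , drop = FALSE]),
                           vertices = rxns)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_ids <- sprintf("g%02d", seq_len(n_genes))
    pos <- integer(n_genes)
    for (s in c("+", "-")) pos[strand == s] <- seq_len(sum(strand == s)) - 1L
    genome <- genome_table("rnd", data.frame(
      gene_id = gene_ids, chromosome = "chr", strand = strand,
      position = pos, stringsAsFactors = FALSE))
    mapping <- lapply(rxns, function(r)
      gene_ids[stats::runif(n_genes) < gene_reaction_rate])
    names(mapping) <- rxns
    corr <- correspondence(mapping, genome)
    D <- expand_gaps_directed(D_raw, delta_d)
    gg <- build_gene_graph(genome, delta_g)
    G <- build_reaction_adjacency(D, gg, corr)
    list(seed = seed, D = D, D_raw = D_raw, G = G, genome = genome,
         correspondence = corr, gene_graph = gg)
  })
}

#' Brute-force maximum-span supported trail oracle
#'
#' Exhaustive depth-first enumeration of every arc-distinct walk of `D`,
#' reporting the maximum span among walks that use `arc` and whose distinct
#' vertices induce a connected subgraph of `G`. Exponential in the number
#' of arcs, hence guarded; intended as an independent correctness oracle on
#' small instances only.
#'
#' @param D a [pathway_graph()].
#' @param G an [und_graph()] on the vertices of `D`.
#' @param arc character vector `c(u, v)`; must be an arc of `D`.
#' @param max_arcs refuse instances with more arcs than this (default 16).
#' @return List with `span` (0 when no supported trail exists) and
#'   `trail` (a witness reaction sequence, or `NULL`).
#' @export
brute_force_max_span <- function(D, G, arc, max_arcs = 16L) {
  if (nrow(D$arcs) > max_arcs)
    stop("instance too large for the brute-force oracle (",
         nrow(D$arcs), " arcs > ", max_arcs, ")")
  if (!has_arc(D, arc)) stop("arc (", arc_key(arc), ") is not an arc of D")
  arcs <- D$arcs
  m <- nrow(arcs)
  target <- which(arcs[, 1L] == arc[[1L]] & arcs[, 2L] == arc[[2L]])
  # self-contained undirected adjacency for the support check
  nb <- stats::setNames(vector("list", length(G$vertices)), G$vertices)
  for (v in G$vertices) nb[[v]] <- character(0)
  if (nrow(G$edges) > 0L) {
    for (i in seq_len(nrow(G$edges))) {
      a <- G$edges[i, 1L]; b <- G$edges[i, 2L]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
  }
  connected <- function(vs) {
    if (length(vs) <= 1L) return(TRUE)
    seen <- vs[[1L]]; queue <- vs[[1L]]
    while (length(queue) > 0L) {
      w <- queue[[1L]]; queue <- queue[-1L]
      for (x in intersect(nb[[w]], vs)) {
        if (!(x %in% seen)) { seen <- c(seen, x); queue <- c(queue, x) }
      }
    }
    length(seen) == length(vs)
  }
  best_span <- 0L
  best_trail <- NULL
  extend <- function(seq_r, used) {
    cur <- seq_r[[length(seq_r)]]
    if (target %in% used) {
      vs <- unique(seq_r)
      if (connected(vs)) {
        sp <- length(vs)
        if (sp > best_span ||
            (sp == best_span && lex_less(seq_r, best_trail))) {
          best_span <<- sp
          best_trail <<- seq_r
        }
      }
    }
    for (k in seq_len(m)) {
      if (k %in% used || arcs[k, 1L] != cur) next
      extend(c(seq_r, arcs[k, 2L]), c(used, k))
    }
  }
  for (v in sort_c(D$vertices)) extend(v, integer(0))
  list(span = best_span, trail = best_trail)
}
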