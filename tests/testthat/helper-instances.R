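# Shared fixtures built in code.

# Small genome mirroring the E. coli mur cluster layout: seven consecutive
# genes on the plus strand, one of them (b0089) not enzyme-coding.
mur_genome <- function() {
  genome_table("eco", data.frame(
    gene_id = c("b0085", "b0086", "b0087", "b0088", "b0089", "b0090",
                "b0091"),
    chromosome = "chr", strand = "+", position = 0:6,
    stringsAsFactors = FALSE))
}

mur_correspondence <- function(genome = mur_genome()) {
  correspondence(list(Ra = "b0085", Rb = "b0086", Rc = "b0087",
                      Rd = "b0088", Re = "b0090", Rf = "b0091"),
                 genome)
}

# Deterministic sweep of random instances small enough for the brute-force
# oracle: at most 8 reactions and 14 arcs.
oracle_instances <- function(n, base_seed = 1000L) {
  out <- list()
  s <- base_seed
  while (length(out) < n) {
    s <- s + 1L
    params <- random_instance(s, n_reactions = 4L + (s %% 5L),
                              arc_density = 0.2 + (s %% 7L) / 25,
                              n_genes = 5L + (s %% 6L),
                              gene_reaction_rate = 0.2 + (s %% 5L) / 12)
    if (nrow(params$D$arcs) >= 1L && nrow(params$D$arcs) <= 14L)
      out[[length(out) + 1L]] <- params
  }
  out
}

# Writes a KGML file realising exactly the arcs of D by giving every arc
# its own linking compound; returns the file path.
write_kgml_for <- function(D, path, id = "syn00001") {
  lines <- c("<?xml version=\"1.0\"?>",
             sprintf("<pathway name=\"path:%s\" title=\"synthetic\">", id))
  arcs <- D$arcs
  subs <- stats::setNames(vector("list", length(D$vertices)), D$vertices)
  prods <- subs
  if (nrow(arcs) > 0L) {
    for (i in seq_len(nrow(arcs))) {
      cpd <- sprintf("cpd:C%03d", i)
      prods[[arcs[i, 1L]]] <- c(prods[[arcs[i, 1L]]], cpd)
      subs[[arcs[i, 2L]]] <- c(subs[[arcs[i, 2L]]], cpd)
    }
  }
  k <- 0L
  for (r in D$vertices) {
    k <- k + 1L
    lines <- c(lines, sprintf(
      "<reaction id=\"%d\" name=\"rn:%s\" type=\"irreversible\">", k, r))
    for (s in subs[[r]])
      lines <- c(lines, sprintf("<substrate id=\"0\" name=\"%s\"/>", s))
    for (p in prods[[r]])
      lines <- c(lines, sprintf("<product id=\"0\" name=\"%s\"/>", p))
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</pathway>")
  writeLines(lines, path)
  path
}

table1_pooled <- function(fx = table1_instance()) {
  list(S = species_data(fx$genomes$S, fx$correspondences$S, fx$records$S),
       S1 = species_data(fx$genomes$S1, fx$correspondences$S1,
                         fx$records$S1))
}
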