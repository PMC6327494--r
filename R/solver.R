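# Exact maximum-span supported trail solver. For an arc (u,v) of D it
# returns one trail of maximum span through (u,v) whose distinct reactions
# induce a connected subgraph of G, or an empty solution when none exists.

# Lexicographic comparison of two reaction sequences under byte ordering;
# a strict prefix precedes its extensions.
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[[i]] != b[[i]])
      return(sort(c(a[[i]], b[[i]]), method = "radix")[[1L]] == a[[i]])
  }
  length(a) < length(b)
}

#' Solution-preserving graph reduction
#'
#' Reduces `D` and `G` to a cover set of the arc `(u, v)`: vertices that
#' provably cannot belong to any supported trail through the arc are
#' discarded. The pruning is a conservative fixpoint: a vertex (other than
#' `u`, `v`) survives only while it is connected to `u` in the underlying
#' undirected restriction of `D` and connected to `u` or `v` in the
#' restriction of `G`. Both conditions are necessary for membership in a
#' supported trail through the arc, so the reduction preserves the solution.
#'
#' @param D a [pathway_graph()].
#' @param G an [und_graph()] on the vertices of `D`.
#' @param arc character vector `c(u, v)`, an arc of `D`.
#' @return List with reduced components `D` and `G`.
#' @export
graph_reduction <- function(D, G, arc) {
  if (!has_arc(D, arc))
    stop("arc (", arc_key(arc), ") is not an arc of D")
  u <- arc[[1L]]; v <- arc[[2L]]
  W <- D$vertices
  repeat {
    dd <- und_graph(W, D$arcs[D$arcs[, 1L] %in% W & D$arcs[, 2L] %in% W, ,
                              drop = FALSE])
    comps_d <- und_components(dd)
    comp_d <- unlist(comps_d[vapply(comps_d, function(cc) u %in% cc,
                                    logical(1))], use.names = FALSE)
    comps_g <- und_components(G, W)
    comp_g <- unlist(comps_g[vapply(comps_g,
                                    function(cc) u %in% cc || v %in% cc,
                                    logical(1))], use.names = FALSE)
    keep <- sort_c(unique(c(u, v, intersect(comp_d, comp_g))))
    if (identical(keep, sort_c(W))) break
    W <- keep
  }
  list(D = pg_induce(D, W), G = und_induce(G, W))
}

#' Is a trail supported by G?
#'
#' A trail is supported when the subgraph of `G` induced by its distinct
#' reactions is connected. Single-vertex and empty trails are supported.
#'
#' @param t a [trail()] or character vector of reactions.
#' @param G an [und_graph()].
#' @return Logical scalar.
#' @export
is_supported <- function(t, G) {
  if (inherits(t, "trail")) t <- t$reactions
  und_connected(G, unique(as.character(t)))
}

#' Maximum-span supported trail through an arc
#'
#' Exact solver: finds a trail of maximum span in `D` passing through `arc`
#' whose distinct reactions induce a connected subgraph of `G`. The search
#' runs in the line graph of the reduced instance: simple paths are
#' enumerated within each strongly connected component, and candidate
#' solutions are assembled by concatenating stored partial paths along
#' paths of the condensation graph that traverse the component holding the
#' arc. Exactly one trail is returned even when several attain the maximum
#' (ties go to the lexicographically smallest reaction sequence). When no
#' supported trail through the arc exists the solution is empty (span 0).
#'
#' @param D a [pathway_graph()].
#' @param G an [und_graph()] with the same vertex set as `D`.
#' @param arc character vector `c(u, v)`; must be an arc of `D`.
#' @param deadline optional absolute `proc.time()` elapsed-seconds deadline;
#'   exceeding it raises a `trailspan_timeout` condition.
#' @return An object of class `masst_solution`: list with `trail` (a
#'   [trail()] or `NULL`), `span`, `through_arc` and `supported`.
#' @examples
#' fx <- fig1_instance()
#' max_span_trail(fx$D, fx$G, c("r1", "r2"))$span # 8
#' @export
max_span_trail <- function(D, G, arc, deadline = NULL) {
  arc <- as.character(arc)
  if (!has_arc(D, arc))
    stop("arc (", arc_key(arc), ") is not an arc of D")
  if (!setequal(G$vertices, D$vertices))
    stop("G must share the vertex set of D")
  red <- graph_reduction(D, G, arc)
  Dr <- red$D; Gr <- red$G
  L <- line_graph(Dr)
  C <- condensation(L)
  A <- access_points(L, C)
  B <- best_partial_paths(L, C, A, deadline)
  aid <- arc_key(arc)
  a_scc <- unname(C$membership[[aid]])

  preds <- stats::setNames(vector("list", length(C$sccs)), names(C$sccs))
  succs <- preds
  for (nm in names(preds)) { preds[[nm]] <- character(0); succs[[nm]] <- character(0) }
  if (nrow(C$arcs) > 0L) {
    for (i in seq_len(nrow(C$arcs))) {
      succs[[C$arcs[i, 1L]]] <- c(succs[[C$arcs[i, 1L]]], C$arcs[i, 2L])
      preds[[C$arcs[i, 2L]]] <- c(preds[[C$arcs[i, 2L]]], C$arcs[i, 1L])
    }
    succs <- lapply(succs, sort_c)
    preds <- lapply(preds, sort_c)
  }
  # all condensation paths ending at / starting from the arc's SCC
  walk <- function(start, nbrs) {
    acc <- list()
    grow <- function(path) {
      acc[[length(acc) + 1L]] <<- path
      for (nb in nbrs[[path[[length(path)]]]]) grow(c(path, nb))
    }
    grow(start)
    acc
  }
  prefixes <- lapply(walk(a_scc, preds), rev)   # end at a_scc
  suffixes <- walk(a_scc, succs)                # start at a_scc

  best_span <- 0L
  best_trail <- NULL
  consider <- function(p) {
    tr <- trail_from_line_path(p)
    sp <- trail_span(tr)
    if (sp < best_span) return(invisible(NULL))
    if (!is_supported(tr, Gr)) return(invisible(NULL))
    if (sp > best_span ||
        (sp == best_span && lex_less(tr$reactions, best_trail$reactions))) {
      best_span <<- sp
      best_trail <<- tr
    }
    invisible(NULL)
  }

  for (pre in prefixes) {
    for (suf in suffixes) {
      Q <- c(pre[-length(pre)], suf)
      memo <- new.env(parent = emptyenv())
      assemble <- function(idx, start) {
        key <- paste(idx, if (is.null(start)) "" else start)
        if (!is.null(memo[[key]])) return(memo[[key]])
        check_deadline(deadline)
        X <- Q[[idx]]
        sources <- if (is.null(start)) sort_c(names(B[[X]])) else start
        out <- list()
        for (s in sources) {
          dest_map <- B[[X]][[s]]
          if (is.null(dest_map)) next
          if (idx == length(Q)) {
            for (paths in dest_map) for (p in paths) {
              if (X == a_scc && !(aid %in% p)) next
              out[[length(out) + 1L]] <- p
            }
          } else {
            conn <- C$cross_arcs[[paste(X, Q[[idx + 1L]], sep = "|")]]
            if (is.null(conn)) next
            for (i in seq_len(nrow(conn))) {
              paths <- dest_map[[conn[i, 1L]]]
              if (is.null(paths)) next
              tails <- assemble(idx + 1L, conn[i, 2L])
              for (p in paths) {
                if (X == a_scc && !(aid %in% p)) next
                for (q in tails) out[[length(out) + 1L]] <- c(p, q)
              }
            }
          }
        }
        memo[[key]] <- out
        out
      }
      for (p in assemble(1L, NULL)) consider(p)
    }
  }
  structure(list(trail = best_trail, span = best_span, through_arc = arc,
                 supported = !is.null(best_trail)),
            class = "masst_solution")
}

#' @export
print.masst_solution <- function(x, ...) {
  if (is.null(x$trail)) {
    cat("<masst_solution> empty (no supported trail through ",
        arc_key(x$through_arc), ")\n", sep = "")
  } else {
    cat("<masst_solution> through ", arc_key(x$through_arc), ": (",
        paste(x$trail$reactions, collapse = ", "), "), span ", x$span,
        "\n", sep = "")
  }
  invisible(x)
}

#' Genomic consistency of a trail
#'
#' Checks that a trail also makes sense at the gene level: true when some
#' selection of one or more catalyzing genes per trail reaction induces a
#' connected subgraph of the gene-neighborhood graph. A reaction with no
#' mapped genes cannot anchor to any genomic neighborhood, so the check
#' fails. The search is polynomial: a qualifying selection exists exactly
#' when one connected component of the candidate-gene subgraph covers every
#' trail reaction.
#'
#' @param t a [trail()] or character vector of reactions.
#' @param gene_graph an [und_graph()] from [build_gene_graph()].
#' @param corr a [correspondence()].
#' @return Logical scalar; when `TRUE`, the attribute `"genes"` holds the
#'   sorted gene set of the witnessing component.
#' @export
genomic_consistency <- function(t, gene_graph, corr) {
  if (inherits(t, "trail")) t <- t$reactions
  rxns <- unique(as.character(t))
  if (length(rxns) == 0L) return(FALSE)
  gsets <- lapply(rxns, function(r) corr_genes(corr, r))
  if (any(lengths(gsets) == 0L)) return(FALSE)
  pool <- sort_c(unique(unlist(gsets, use.names = FALSE)))
  for (comp in und_components(gene_graph, pool)) {
    covers <- all(vapply(gsets, function(gs)
      length(intersect(gs, comp)) > 0L, logical(1)))
    if (covers) {
      used <- comp[vapply(comp, function(g)
        any(vapply(gsets, function(gs) g %in% gs, logical(1))), logical(1))]
      return(structure(TRUE, genes = sort_c(used)))
    }
  }
  FALSE
}

# TRUE when `a` is a contiguous proper subsequence of `b`.
is_contiguous_subtrail <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || na >= nb) return(FALSE)
  for (start in seq_len(nb - na + 1L)) {
    if (identical(b[seq(start, start + na - 1L)], a)) return(TRUE)
  }
  FALSE
}

#' Solve every arc of a pathway
#'
#' Runs the maximum-span supported trail solver once per arc of `D`,
#' discards solutions that fail the gene-level consistency check, collapses
#' duplicates, and drops trails that are contiguous sub-trails of another
#' reported trail, leaving one record per maximal trail.
#'
#' @param D a [pathway_graph()] (already gap-expanded if desired).
#' @param G an [und_graph()] with the vertices of `D`.
#' @param gene_graph the gene-neighborhood [und_graph()].
#' @param corr a [correspondence()].
#' @param species,pathway provenance strings stored in the records.
#' @param delta_d,delta_g gap parameters stored in the records.
#' @param timeout wall-clock seconds allowed for the whole pathway
#'   (default `Inf`).
#' @return List with `records` (data frame: species, pathway, delta_d,
#'   delta_g, reactions, span, genes), `timed_out` (logical) and
#'   `blacklist` (logical: timed out before producing any record).
#' @export
solve_pathway <- function(D, G, gene_graph, corr,
                          species = NA_character_, pathway = NA_character_,
                          delta_d = 0L, delta_g = 0L, timeout = Inf) {
  stopifnot(timeout > 0)
  deadline <- if (is.finite(timeout)) proc.time()[["elapsed"]] + timeout
              else NULL
  sols <- list()
  timed_out <- FALSE
  if (nrow(D$arcs) > 0L) {
    for (i in seq_len(nrow(D$arcs))) {
      arc <- D$arcs[i, ]
      res <- tryCatch(max_span_trail(D, G, arc, deadline),
                      trailspan_timeout = function(e) e)
      if (inherits(res, "trailspan_timeout")) { timed_out <- TRUE; break }
      if (!is.null(res$trail)) sols[[length(sols) + 1L]] <- res$trail
    }
  }
  kept <- list()
  genes <- list()
  for (tr in sols) {
    ok <- genomic_consistency(tr, gene_graph, corr)
    if (!isTRUE(c(ok))) next
    key <- paste(tr$reactions, collapse = ";")
    if (!is.null(kept[[key]])) next
    kept[[key]] <- tr$reactions
    genes[[key]] <- attr(ok, "genes")
  }
  seqs <- unname(kept)
  maximal <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i != j && is_contiguous_subtrail(seqs[[i]], seqs[[j]])) {
        maximal[[i]] <- FALSE
        break
      }
    }
  }
  keys <- if (length(kept) > 0L) names(kept)[maximal] else character(0)
  records <- data.frame(
    species = rep(as.character(species), length(keys)),
    pathway = rep(as.character(pathway), length(keys)),
    delta_d = rep(as.integer(delta_d), length(keys)),
    delta_g = rep(as.integer(delta_g), length(keys)),
    reactions = keys,
    span = vapply(keys, function(k) trail_span(kept[[k]]), integer(1)),
    genes = vapply(keys, function(k) paste(genes[[k]], collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
  records <- records[order_c(-records$span, records$reactions), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, timed_out = timed_out,
       blacklist = timed_out && nrow(records) == 0L)
}
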