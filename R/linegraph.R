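# Line-graph formulation: trail search in D becomes path search in L(D).
# Vertices of L(D) are arcs of D; SCC condensation then confines exhaustive
# path enumeration to within strongly connected components.

check_deadline <- function(deadline) {
  if (!is.null(deadline) && proc.time()[["elapsed"]] > deadline)
    stop(errorCondition("path enumeration exceeded its time budget",
                        class = c("trailspan_timeout", "error", "condition")))
  invisible(NULL)
}

#' Line graph of a pathway graph
#'
#' The line graph \eqn{L(D)} has the arcs of `D` as vertices; an arc runs
#' from \eqn{x = (r, s)} to \eqn{y = (s, t)} whenever both are arcs of `D`
#' chaining through the middle vertex \eqn{s}. Vertex order is deterministic
#' (lexicographic in the underlying arc).
#'
#' @param D a [pathway_graph()].
#' @return An object of class `line_graph` with components `vertices` (data
#'   frame `id`, `from`, `to`) and `arcs` (two-column matrix of vertex ids).
#' @export
line_graph <- function(D) {
  stopifnot(inherits(D, "pathway_graph"))
  arcs <- D$arcs
  verts <- data.frame(id = if (nrow(arcs)) arc_key(arcs[, 1L], arcs[, 2L])
                      else character(0),
                      from = arcs[, 1L], to = arcs[, 2L],
                      stringsAsFactors = FALSE)
  larcs <- list()
  if (nrow(verts) > 1L) {
    by_from <- split(verts$id, verts$from)
    for (i in seq_len(nrow(verts))) {
      succ <- by_from[[verts$to[[i]]]]
      if (!is.null(succ))
        for (s in succ) larcs[[length(larcs) + 1L]] <- c(verts$id[[i]], s)
    }
  }
  larcs <- if (length(larcs) > 0L) do.call(rbind, larcs)
           else matrix(character(0), ncol = 2L)
  if (nrow(larcs) > 0L)
    larcs <- larcs[order_c(larcs[, 1L], larcs[, 2L]), , drop = FALSE]
  colnames(larcs) <- c("from", "to")
  structure(list(vertices = verts, arcs = larcs), class = "line_graph")
}

#' @export
print.line_graph <- function(x, ...) {
  cat("<line_graph> ", nrow(x$vertices), " vertices (arcs of D), ",
      nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

# D vertices touched by a set of L-vertex ids.
lpath_dverts <- function(L, ids) {
  sel <- match(ids, L$vertices$id)
  unique(c(L$vertices$from[sel], L$vertices$to[sel]))
}

#' Trail corresponding to a path in the line graph
#'
#' Maps a path \eqn{P = (a_1, ..., a_k)} in \eqn{L(D)}, with
#' \eqn{a_i = (t_{i-1}, t_i)}, back to the trail
#' \eqn{(t_0, t_1, ..., t_k)} in `D`. An empty path maps to an empty trail.
#'
#' @param P a two-column character matrix of consecutive arcs of `D`, or a
#'   character vector of line-graph vertex ids of the form `"from->to"`.
#' @return A [trail()].
#' @examples
#' trail_from_line_path(rbind(c("r3", "r7"), c("r7", "r8"), c("r8", "r3")))
#' @export
trail_from_line_path <- function(P) {
  if (is.character(P) && is.null(dim(P))) {
    if (length(P) == 0L) return(trail())
    parts <- strsplit(P, "->", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed line-graph vertex id: ", P[bad][[1L]])
    P <- do.call(rbind, parts)
  }
  P <- normalize_arcs(P)
  if (nrow(P) == 0L) return(trail())
  if (nrow(P) > 1L) {
    chained <- P[-nrow(P), 2L] == P[-1L, 1L]
    if (!all(chained))
      stop("consecutive line-graph vertices do not chain: ",
           arc_key(P[which(!chained)[[1L]], ]), " then ",
           arc_key(P[which(!chained)[[1L]] + 1L, ]))
  }
  trail(c(P[1L, 1L], P[, 2L]))
}

#' Condensation of a line graph
#'
#' Computes the strongly connected components (SCCs) of \eqn{L(D)} and the
#' acyclic quotient graph obtained by contracting each SCC to one vertex.
#' SCC labels `S1, S2, ...` follow a topological order of the condensation
#' (ties broken by smallest member id), so labelling is deterministic.
#'
#' @param L a [line_graph()].
#' @return An object of class `condensation` with components `membership`
#'   (named character: L-vertex id to SCC label), `sccs` (named list of
#'   member ids), `arcs` (two-column matrix of SCC labels) and `cross_arcs`
#'   (per SCC pair `"P|S"`, the matrix of L-arcs from P to S).
#' @export
condensation <- function(L) {
  stopifnot(inherits(L, "line_graph"))
  ids <- L$vertices$id
  if (length(ids) == 0L)
    return(structure(list(membership = stats::setNames(character(0),
                                                       character(0)),
                          sccs = list(),
                          arcs = matrix(character(0), ncol = 2L),
                          cross_arcs = list()),
                     class = "condensation"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = L$arcs[, 1L], to = L$arcs[, 2L],
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = ids)
  memb <- igraph::components(g, mode = "strong")$membership
  groups <- split(names(memb), memb)
  groups <- lapply(groups, sort_c)
  # arcs between provisional groups
  gid <- stats::setNames(rep(names(groups), lengths(groups)),
                         unlist(groups, use.names = FALSE))
  cross <- matrix(character(0), ncol = 2L)
  if (nrow(L$arcs) > 0L) {
    ga <- cbind(gid[L$arcs[, 1L]], gid[L$arcs[, 2L]])
    cross <- unique(ga[ga[, 1L] != ga[, 2L], , drop = FALSE])
  }
  # deterministic topological labelling (Kahn, smallest member id first)
  reps <- vapply(groups, `[[`, character(1), 1L)
  indeg <- stats::setNames(integer(length(groups)), names(groups))
  if (nrow(cross) > 0L)
    for (i in seq_len(nrow(cross)))
      indeg[[cross[i, 2L]]] <- indeg[[cross[i, 2L]]] + 1L
  avail <- names(indeg)[indeg == 0L]
  topo <- character(0)
  while (length(avail) > 0L) {
    avail <- avail[order_c(reps[avail])]
    nxt <- avail[[1L]]; avail <- avail[-1L]
    topo <- c(topo, nxt)
    if (nrow(cross) > 0L) {
      out <- cross[cross[, 1L] == nxt, 2L]
      for (s in out) {
        indeg[[s]] <- indeg[[s]] - 1L
        if (indeg[[s]] == 0L) avail <- c(avail, s)
      }
    }
  }
  labels <- stats::setNames(paste0("S", seq_along(topo)), topo)
  sccs <- stats::setNames(groups[topo], labels[topo])
  membership <- stats::setNames(labels[gid], names(gid))
  arcs <- matrix(character(0), ncol = 2L)
  cross_arcs <- list()
  if (nrow(cross) > 0L) {
    arcs <- cbind(unname(labels[cross[, 1L]]), unname(labels[cross[, 2L]]))
    arcs <- arcs[order_c(arcs[, 1L], arcs[, 2L]), , drop = FALSE]
    la <- cbind(unname(membership[L$arcs[, 1L]]),
                unname(membership[L$arcs[, 2L]]))
    inter <- la[, 1L] != la[, 2L]
    key <- paste(la[inter, 1L], la[inter, 2L], sep = "|")
    sub <- L$arcs[inter, , drop = FALSE]
    cross_arcs <- lapply(split(seq_along(key), key),
                         function(i) sub[i, , drop = FALSE])
  }
  colnames(arcs) <- c("from", "to")
  structure(list(membership = membership, sccs = sccs, arcs = arcs,
                 cross_arcs = cross_arcs),
            class = "condensation")
}

#' @export
print.condensation <- function(x, ...) {
  cat("<condensation> ", length(x$sccs), " SCCs, ", nrow(x$arcs),
      " arcs\n", sep = "")
  invisible(x)
}

#' Entry and exit points of every SCC
#'
#' For each SCC, the entry points keyed by predecessor SCC are the members
#' receiving an arc from that predecessor; exit points keyed by successor
#' SCC are the members sending an arc into that successor.
#'
#' @param L a [line_graph()].
#' @param C its [condensation()].
#' @return A list with components `entry` and `exit`: nested named lists
#'   `entry[[scc]][[predecessor]]` / `exit[[scc]][[successor]]` of sorted
#'   member ids.
#' @export
access_points <- function(L, C) {
  entry <- stats::setNames(vector("list", length(C$sccs)), names(C$sccs))
  exit <- entry
  for (nm in names(entry)) { entry[[nm]] <- list(); exit[[nm]] <- list() }
  for (key in names(C$cross_arcs)) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1L]]
    arcs <- C$cross_arcs[[key]]
    exit[[pair[[1L]]]][[pair[[2L]]]] <- sort_c(unique(arcs[, 1L]))
    entry[[pair[[2L]]]][[pair[[1L]]]] <- sort_c(unique(arcs[, 2L]))
  }
  list(entry = entry, exit = exit)
}

#' Best partial paths within each SCC
#'
#' Enumerates simple paths inside every SCC of \eqn{L(D)} between the
#' source/destination pairs a condensation-path translation can require.
#' Because an SCC may open or close the translated path, sources and
#' destinations degenerate to all members; when the SCC is internal only
#' entry-to-exit pairs are consulted. For each ordered pair the store keeps
#' one representative per distinct set of traversed line-graph vertices,
#' ranked by span of the corresponding trail (best first, ties by
#' lexicographic trail).
#' Keeping all vertex-set-distinct candidates, not a single best, is what
#' makes later concatenation exact: per-component optima need not compose
#' to a global optimum when components revisit the same reactions.
#'
#' @param L a [line_graph()].
#' @param C its [condensation()].
#' @param A access points from [access_points()] (accepted for interface
#'   symmetry; the full store subsumes them).
#' @param deadline optional absolute `proc.time()` elapsed-seconds deadline.
#' @return Nested named list `store[[scc]][[source]][[destination]]`, each a
#'   list of paths (character vectors of L-vertex ids).
#' @export
best_partial_paths <- function(L, C, A = NULL, deadline = NULL) {
  from_of <- stats::setNames(L$vertices$from, L$vertices$id)
  to_of <- stats::setNames(L$vertices$to, L$vertices$id)
  store <- stats::setNames(vector("list", length(C$sccs)), names(C$sccs))
  for (scc in names(C$sccs)) {
    members <- C$sccs[[scc]]
    inside <- L$arcs[L$arcs[, 1L] %in% members &
                     L$arcs[, 2L] %in% members, , drop = FALSE]
    adj <- stats::setNames(vector("list", length(members)), members)
    for (m in members) adj[[m]] <- character(0)
    if (nrow(inside) > 0L)
      for (i in seq_len(nrow(inside)))
        adj[[inside[i, 1L]]] <- c(adj[[inside[i, 1L]]], inside[i, 2L])
    adj <- lapply(adj, sort_c)
    per_source <- stats::setNames(vector("list", length(members)), members)
    for (s in members) {
      found <- list()
      path <- s
      visited <- stats::setNames(logical(length(members)), members)
      visited[[s]] <- TRUE
      dfs <- function() {
        check_deadline(deadline)
        cur <- path[[length(path)]]
        found[[length(found) + 1L]] <<- path
        for (nb in adj[[cur]]) {
          if (visited[[nb]]) next
          visited[[nb]] <<- TRUE
          path <<- c(path, nb)
          dfs()
          path <<- path[-length(path)]
          visited[[nb]] <<- FALSE
        }
      }
      dfs()
      dests <- vapply(found, function(p) p[[length(p)]], character(1))
      per_dest <- split(found, dests)
      per_dest <- lapply(per_dest, function(paths) {
        spans <- vapply(paths, function(p)
          length(unique(c(from_of[p], to_of[p]))), integer(1))
        # dedup by the set of line-graph vertices used: paths touching the
        # same reactions may still differ in which arcs they traverse, and
        # only some contain the query arc
        keys <- vapply(paths, function(p)
          paste(sort_c(p), collapse = ";"), character(1))
        lex <- vapply(paths, function(p) paste(p, collapse = " "),
                      character(1))
        ord <- order(-spans, lex, method = "radix")
        paths <- paths[ord]; keys <- keys[ord]
        paths[!duplicated(keys)]
      })
      per_source[[s]] <- per_dest
    }
    store[[scc]] <- per_source
  }
  store
}
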