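# Core graph containers: the directed reaction graph D of a pathway and the
# undirected graphs (gene neighborhood G', derived reaction adjacency G).
# All vertex/edge orderings use radix (byte-wise) sorting so that results are
# identical across locales.

sort_c <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

#' Directed reaction graph of a metabolic pathway
#'
#' Builds the directed graph \eqn{D} modeling a metabolic pathway: vertices
#' are reactions and an arc \eqn{(r_i, r_j)} states that \eqn{r_i} produces a
#' metabolite that is a substrate of \eqn{r_j}. The graph is kept simple:
#' duplicate arcs are collapsed and self-loops are dropped, which is how
#' KGML-derived duplicates are normalised.
#'
#' @param arcs two-column character matrix or data frame (`from`, `to`), or
#'   `NULL` for an arcless graph.
#' @param vertices optional character vector of additional (possibly
#'   isolated) vertices; endpoints of `arcs` are always included.
#' @return An object of class `pathway_graph` with components `vertices`
#'   (sorted character vector) and `arcs` (two-column character matrix in
#'   lexicographic order).
#' @examples
#' D <- pathway_graph(rbind(c("r1", "r2"), c("r2", "r3")))
#' n_arcs(D)
#' @export
pathway_graph <- function(arcs = NULL, vertices = NULL) {
  arcs <- normalize_arcs(arcs)
  if (nrow(arcs) > 0L) {
    keep <- arcs[, 1L] != arcs[, 2L]
    arcs <- arcs[keep, , drop = FALSE]
    arcs <- unique(arcs)
    arcs <- arcs[order_c(arcs[, 1L], arcs[, 2L]), , drop = FALSE]
  }
  vertices <- sort_c(unique(c(as.character(vertices), as.vector(arcs))))
  if (any(is.na(vertices)) || any(!nzchar(vertices)))
    stop("vertex identifiers must be non-empty strings")
  structure(list(vertices = vertices, arcs = arcs), class = "pathway_graph")
}

normalize_arcs <- function(arcs) {
  if (is.null(arcs))
    return(matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (length(arcs) == 0L)
    return(matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  if (is.null(dim(arcs)) && length(arcs) == 2L) arcs <- matrix(arcs, ncol = 2L)
  if (ncol(arcs) != 2L) stop("arcs must have two columns (from, to)")
  mode(arcs) <- "character"
  if (any(is.na(arcs)) || any(!nzchar(arcs)))
    stop("arc endpoints must be non-empty strings")
  dimnames(arcs) <- list(NULL, c("from", "to"))
  arcs
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", length(x$vertices), " reactions, ",
      nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

#' Number of arcs of a pathway graph
#' @param D a [pathway_graph()].
#' @return Integer arc count.
#' @export
n_arcs <- function(D) nrow(D$arcs)

#' Test whether an ordered vertex pair is an arc of D
#' @param D a [pathway_graph()].
#' @param arc character vector of length two `c(from, to)`.
#' @return Logical scalar.
#' @export
has_arc <- function(D, arc) {
  stopifnot(length(arc) == 2L)
  any(D$arcs[, 1L] == arc[[1L]] & D$arcs[, 2L] == arc[[2L]])
}

arc_key <- function(from, to = NULL) {
  if (is.null(to)) { to <- from[[2L]]; from <- from[[1L]] }
  paste0(from, "->", to)
}

pg_igraph <- function(D) {
  igraph::graph_from_data_frame(
    data.frame(from = D$arcs[, 1L], to = D$arcs[, 2L],
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = D$vertices)
}

# Induced subgraph of D on a vertex subset.
pg_induce <- function(D, keep) {
  keep <- intersect(D$vertices, keep)
  arcs <- D$arcs[D$arcs[, 1L] %in% keep & D$arcs[, 2L] %in% keep, ,
                 drop = FALSE]
  pathway_graph(arcs, vertices = keep)
}

#' Undirected graph container
#'
#' Shared representation for the gene-neighborhood graph \eqn{G'} and the
#' reaction-adjacency graph \eqn{G}. Edges are unordered pairs; loops and
#' duplicates are discarded.
#'
#' @param vertices character vector of vertex identifiers.
#' @param edges two-column character matrix of edges, or `NULL`.
#' @return An object of class `und_graph` with sorted `vertices` and a
#'   canonically ordered two-column `edges` matrix.
#' @export
und_graph <- function(vertices = NULL, edges = NULL) {
  edges <- normalize_arcs(edges)
  colnames(edges) <- c("a", "b")
  if (nrow(edges) > 0L) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    edges <- unique(edges)
    edges <- edges[order_c(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  vertices <- sort_c(unique(c(as.character(vertices), as.vector(edges))))
  structure(list(vertices = vertices, edges = edges), class = "und_graph")
}

#' @export
print.und_graph <- function(x, ...) {
  cat("<und_graph> ", length(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Complete undirected graph on a vertex set
#' @param vertices character vector.
#' @return An [und_graph()] with every unordered pair as an edge.
#' @export
complete_und_graph <- function(vertices) {
  vertices <- sort_c(unique(as.character(vertices)))
  n <- length(vertices)
  if (n < 2L) return(und_graph(vertices))
  idx <- utils::combn(n, 2L)
  und_graph(vertices, cbind(vertices[idx[1L, ]], vertices[idx[2L, ]]))
}

und_induce <- function(G, keep) {
  keep <- intersect(G$vertices, keep)
  edges <- G$edges[G$edges[, 1L] %in% keep & G$edges[, 2L] %in% keep, ,
                   drop = FALSE]
  und_graph(keep, edges)
}

# Adjacency list (names = vertices, values = sorted neighbor vectors).
und_adjacency <- function(G) {
  adj <- stats::setNames(vector("list", length(G$vertices)), G$vertices)
  for (v in G$vertices) adj[[v]] <- character(0)
  if (nrow(G$edges) > 0L) {
    for (i in seq_len(nrow(G$edges))) {
      a <- G$edges[i, 1L]; b <- G$edges[i, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, sort_c)
  }
  adj
}

# Connected components of an und_graph restricted to `subset`.
# Returns a list of sorted character vectors.
und_components <- function(G, subset = NULL) {
  verts <- if (is.null(subset)) G$vertices else intersect(G$vertices, subset)
  if (length(verts) == 0L) return(list())
  keep <- G$edges[, 1L] %in% verts & G$edges[, 2L] %in% verts
  edges <- G$edges[keep, , drop = FALSE]
  adj <- stats::setNames(vector("list", length(verts)), verts)
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- stats::setNames(logical(length(verts)), verts)
  comps <- list()
  for (v in sort_c(verts)) {
    if (seen[[v]]) next
    queue <- v
    seen[[v]] <- TRUE
    comp <- character(0)
    while (length(queue) > 0L) {
      w <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, w)
      for (nb in adj[[w]]) {
        if (!seen[[nb]]) { seen[[nb]] <- TRUE; queue <- c(queue, nb) }
      }
    }
    comps[[length(comps) + 1L]] <- sort_c(comp)
  }
  comps
}

und_connected <- function(G, subset) {
  subset <- unique(subset)
  if (length(subset) <= 1L) return(TRUE)
  if (!all(subset %in% G$vertices)) return(FALSE)
  comps <- und_components(G, subset)
  length(comps) == 1L
}
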