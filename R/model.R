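# Genome tables, the reaction-gene correspondence, gap expansion, and the
# derived reaction-adjacency graph G.

#' Genome table
#'
#' Ordered catalogue of the protein-coding genes of one species. Genes are
#' positioned by ordinal along each (chromosome, strand) group; positions
#' within a group must be the consecutive integers 0, 1, 2, ... Non-enzyme
#' genes belong in the table too: they occupy a position and therefore count
#' toward gap distances when neighborhoods are computed.
#'
#' @param species species code (KEGG-style three/four letter identifier).
#' @param genes data frame with columns `gene_id`, `chromosome`, `strand`
#'   (`"+"` or `"-"`), `position` (non-negative integer ordinal).
#' @param circular named logical vector flagging circular chromosomes
#'   (default: all linear). Unnamed scalar recycles to every chromosome.
#' @return An object of class `genome_table`.
#' @export
genome_table <- function(species, genes, circular = FALSE) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "chromosome", "strand", "position")
  if (!all(req %in% names(genes)))
    stop("genome table needs columns: ", paste(req, collapse = ", "))
  genes <- genes[req]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$strand <- as.character(genes$strand)
  genes$position <- as.integer(genes$position)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in genome table")
  grp <- paste(genes$chromosome, genes$strand, sep = "\r")
  for (g in unique(grp)) {
    pos <- sort(genes$position[grp == g])
    if (!identical(pos, seq_along(pos) - 1L))
      stop("positions within a (chromosome, strand) group must be ",
           "consecutive ordinals starting at 0")
  }
  genes <- genes[order_c(genes$chromosome, genes$strand, genes$position), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  chroms <- sort_c(unique(genes$chromosome))
  if (is.null(names(circular))) {
    circ <- stats::setNames(rep(isTRUE(circular[[1L]]), length(chroms)), chroms)
  } else {
    circ <- stats::setNames(rep(FALSE, length(chroms)), chroms)
    known <- intersect(names(circular), chroms)
    circ[known] <- as.logical(circular[known])
  }
  structure(list(species = as.character(species), genes = genes,
                 circular = circ),
            class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("<genome_table> species ", x$species, ": ", nrow(x$genes),
      " genes on ", length(unique(x$genes$chromosome)), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Reaction-to-genes correspondence
#'
#' The correspondence function of the model: for each reaction, the set of
#' genes of the species whose products catalyze it. Reactions may map to an
#' empty gene set.
#'
#' @param mapping named list; names are reaction identifiers, values
#'   character vectors of gene identifiers (possibly empty).
#' @param genome optional [genome_table()] used to check that every mapped
#'   gene exists.
#' @return An object of class `correspondence` (a named list of sorted gene
#'   vectors).
#' @export
correspondence <- function(mapping = list(), genome = NULL) {
  if (length(mapping) > 0L && is.null(names(mapping)))
    stop("mapping must be a named list (reaction -> genes)")
  mapping <- lapply(mapping, function(g) sort_c(unique(as.character(g))))
  mapping <- mapping[sort_c(names(mapping))]
  if (!is.null(genome)) {
    all_genes <- unique(unlist(mapping, use.names = FALSE))
    missing <- setdiff(all_genes, genome$genes$gene_id)
    if (length(missing) > 0L)
      stop("correspondence maps unknown genes: ",
           paste(missing, collapse = ", "))
  }
  structure(mapping, class = "correspondence")
}

#' Genes catalyzing a reaction
#' @param corr a [correspondence()].
#' @param reaction reaction identifier.
#' @return Character vector (empty when the reaction is not mapped).
#' @export
corr_genes <- function(corr, reaction) {
  g <- corr[[reaction]]
  if (is.null(g)) character(0) else g
}

# Number of table rows strictly between two ordinals on one strand group of
# n genes; for circular chromosomes the shorter way around is taken.
intervening_count <- function(p1, p2, n, circular) {
  d <- abs(p1 - p2)
  direct <- d - 1L
  if (!circular) return(direct)
  min(direct, n - d - 1L)
}

#' Gene-neighborhood graph
#'
#' Builds the undirected graph \eqn{G'} over all genes of a genome: two genes
#' are connected when they lie on the same strand of the same chromosome with
#' at most `delta_g` other genes between their positions. With `delta_g = 0`
#' only immediately consecutive genes are linked. On chromosomes flagged
#' circular the gene order wraps around the origin.
#'
#' @param genome a [genome_table()].
#' @param delta_g non-negative integer gap parameter (documented operating
#'   range 0-3).
#' @return An [und_graph()] whose vertices are all gene identifiers.
#' @export
build_gene_graph <- function(genome, delta_g = 0L) {
  stopifnot(inherits(genome, "genome_table"))
  if (length(delta_g) != 1L || is.na(delta_g) || delta_g < 0)
    stop("delta_g must be a single non-negative integer")
  delta_g <- as.integer(delta_g)
  genes <- genome$genes
  edges <- list()
  grp <- paste(genes$chromosome, genes$strand, sep = "\r")
  for (g in unique(grp)) {
    sel <- genes[grp == g, , drop = FALSE]
    sel <- sel[order(sel$position), , drop = FALSE]
    n <- nrow(sel)
    if (n < 2L) next
    circ <- isTRUE(genome$circular[[sel$chromosome[[1L]]]])
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        gap <- intervening_count(sel$position[[i]], sel$position[[j]], n, circ)
        if (gap <= delta_g)
          edges[[length(edges) + 1L]] <- c(sel$gene_id[[i]], sel$gene_id[[j]])
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else NULL
  und_graph(genes$gene_id, edges)
}

#' Reaction-adjacency graph derived from gene neighborhood
#'
#' Builds the undirected graph \eqn{G} on the vertex set of the pathway
#' graph: reactions \eqn{r_i} and \eqn{r_j} are linked when some gene
#' catalyzing \eqn{r_i} is adjacent in the gene-neighborhood graph to a gene
#' catalyzing \eqn{r_j}, or when the two reactions share a catalyzing gene
#' (a gene is trivially in its own neighborhood). Reactions with no mapped
#' genes remain isolated vertices.
#'
#' @param D a [pathway_graph()].
#' @param gene_graph an [und_graph()] from [build_gene_graph()].
#' @param corr a [correspondence()] defined over the reactions of `D`.
#' @return An [und_graph()] with exactly the vertices of `D`.
#' @export
build_reaction_adjacency <- function(D, gene_graph, corr) {
  stopifnot(inherits(D, "pathway_graph"), inherits(gene_graph, "und_graph"))
  verts <- D$vertices
  gsets <- lapply(verts, function(r) corr_genes(corr, r))
  names(gsets) <- verts
  adj <- und_adjacency(gene_graph)
  closed <- lapply(gsets, function(gs) {
    nb <- unlist(adj[intersect(gs, names(adj))], use.names = FALSE)
    unique(c(gs, nb))
  })
  edges <- list()
  n <- length(verts)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (length(gsets[[i]]) == 0L) next
      for (j in seq(i + 1L, n)) {
        if (length(gsets[[j]]) == 0L) next
        if (length(intersect(closed[[i]], gsets[[j]])) > 0L)
          edges[[length(edges) + 1L]] <- c(verts[[i]], verts[[j]])
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else NULL
  und_graph(verts, edges)
}

#' Gap expansion of the reaction graph
#'
#' Adds an arc \eqn{(a, c)} to `D` whenever a directed path from \eqn{a} to
#' \eqn{c} exists with at most `delta_d` intermediate reactions, so that
#' trails may "skip" up to `delta_d` reactions. Distances are directed:
#' skipping follows the direction of metabolite flow. `delta_d = 0` returns
#' `D` unchanged.
#'
#' @param D a [pathway_graph()].
#' @param delta_d non-negative integer gap parameter.
#' @return A [pathway_graph()] with the augmented arc set.
#' @export
expand_gaps_directed <- function(D, delta_d = 0L) {
  stopifnot(inherits(D, "pathway_graph"))
  if (length(delta_d) != 1L || is.na(delta_d) || delta_d < 0)
    stop("delta_d must be a single non-negative integer")
  delta_d <- as.integer(delta_d)
  if (delta_d == 0L || nrow(D$arcs) == 0L) return(D)
  g <- pg_igraph(D)
  dm <- igraph::distances(g, mode = "out")
  idx <- which(dm >= 1 & dm <= delta_d + 1, arr.ind = TRUE)
  arcs <- cbind(rownames(dm)[idx[, 1L]], colnames(dm)[idx[, 2L]])
  pathway_graph(arcs, vertices = D$vertices)
}

#' Reaction trail
#'
#' A trail is a walk in the pathway graph that may repeat vertices but never
#' repeats an arc. When `D` is supplied the sequence is validated against its
#' arc set and checked for arc-distinctness.
#'
#' @param reactions character vector of reaction identifiers in walk order
#'   (may be empty).
#' @param D optional [pathway_graph()] to validate against.
#' @param provenance optional list (species, pathway, delta_d, delta_g).
#' @return An object of class `trail`.
#' @export
trail <- function(reactions = character(0), D = NULL, provenance = NULL) {
  reactions <- as.character(reactions)
  if (!is.null(D) && length(reactions) >= 2L) {
    steps <- cbind(reactions[-length(reactions)], reactions[-1L])
    keys <- arc_key(steps[, 1L], steps[, 2L])
    if (anyDuplicated(keys))
      stop("trail repeats an arc")
    ok <- vapply(seq_len(nrow(steps)), function(i) has_arc(D, steps[i, ]),
                 logical(1))
    if (!all(ok))
      stop("trail uses pairs that are not arcs of D: ",
           paste(keys[!ok], collapse = ", "))
  }
  structure(list(reactions = reactions, provenance = provenance),
            class = "trail")
}

#' @export
print.trail <- function(x, ...) {
  cat("<trail> (", paste(x$reactions, collapse = ", "), "), span ",
      trail_span(x), "\n", sep = "")
  invisible(x)
}

#' Span of a trail
#'
#' The span is the number of distinct reactions visited, the quantity the
#' solver maximises. Repeated vertices count once.
#'
#' @param t a [trail()] or a character vector of reactions.
#' @return Integer span.
#' @examples
#' trail_span(trail(c("r2", "r3", "r7", "r8", "r3", "r4"))) # 5
#' @export
trail_span <- function(t) {
  if (inherits(t, "trail")) t <- t$reactions
  length(unique(as.character(t)))
}
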