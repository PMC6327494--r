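# Interspecies grouping: per-species trails are pooled as reaction sets and
# compared across a species panel, yielding the by-reactions table (symbols
# x / . / blank) and the by-genes table (symbols x / .).

#' Reaction set of a trail
#'
#' Trails are compared across species as unordered reaction sets: order and
#' repetition are discarded.
#'
#' @param t a [trail()] or nonempty character vector of reactions.
#' @return Sorted character vector of distinct reactions.
#' @export
reaction_set <- function(t) {
  if (inherits(t, "trail")) t <- t$reactions
  t <- as.character(t)
  if (length(t) == 0L) stop("cannot take the reaction set of an empty trail")
  sort_c(unique(t))
}

rset_key <- function(rs) paste(rs, collapse = ";")

#' Pool trail records into reaction sets
#'
#' Collects the trails of one species -- over every pathway and every gap
#' parameter combination -- into its pool of reaction sets. Records whose
#' trails reduce to the same set are merged.
#'
#' @param records data frame of trail records with a `reactions` column of
#'   semicolon-joined reaction sequences (as written by [solve_pathway()]).
#' @return Named list of sorted reaction vectors, keyed by the canonical
#'   semicolon-joined set; ordered by key.
#' @export
pool_reaction_sets <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(stats::setNames(list(), character(0)))
  sets <- lapply(strsplit(records$reactions, ";", fixed = TRUE),
                 reaction_set)
  keys <- vapply(sets, rset_key, character(1))
  sets <- sets[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  stats::setNames(sets, keys)[order_c(keys)]
}

# Row lookup helpers on a genome table.
genome_row <- function(genome, gene) {
  i <- match(gene, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene)
  genome$genes[i, , drop = FALSE]
}

#' Are genes neighboring on the genome?
#'
#' Genes are neighboring when they all lie on one strand of one chromosome
#' and can be ordered along it with every consecutive pair separated by at
#' most `gap` other genes (default 3, the grouping-stage rule). Non-enzyme
#' genes count toward the separation. On circular chromosomes the order may
#' wrap, in which case the largest inter-gene gap is the one left open.
#'
#' @param genome a [genome_table()].
#' @param gene_ids character vector of gene identifiers (all must exist).
#' @param gap maximum number of intervening genes between consecutive
#'   members.
#' @return Logical scalar.
#' @export
genes_neighboring <- function(genome, gene_ids, gap = 3L) {
  gene_ids <- unique(as.character(gene_ids))
  rows <- do.call(rbind, lapply(gene_ids, function(g) genome_row(genome, g)))
  if (length(gene_ids) <= 1L) return(TRUE)
  if (length(unique(rows$chromosome)) > 1L ||
      length(unique(rows$strand)) > 1L) return(FALSE)
  n <- sum(genome$genes$chromosome == rows$chromosome[[1L]] &
           genome$genes$strand == rows$strand[[1L]])
  circ <- isTRUE(genome$circular[[rows$chromosome[[1L]]]])
  pos <- sort(rows$position)
  gaps <- diff(pos) - 1L
  if (circ) {
    wrap <- n - (max(pos) - min(pos)) - 1L
    gaps <- sort(c(gaps, wrap), decreasing = TRUE)[-1L]  # open the largest
  }
  all(gaps <= gap)
}

# Clusters of `gene_ids` per (chromosome, strand): maximal runs where
# consecutive members are separated by at most `gap` table rows. Any chain
# of neighboring genes drawn from `gene_ids` lies within one such run, and
# taking a whole run never breaks the chain condition, so runs are exactly
# the maximal neighboring groups. Returns a list of data frames (one run
# each) ordered by chromosome, strand, first position.
neighbor_runs <- function(genome, gene_ids, gap = 3L) {
  gene_ids <- unique(as.character(gene_ids))
  missing <- setdiff(gene_ids, genome$genes$gene_id)
  if (length(missing) > 0L)
    stop("unknown gene: ", paste(missing, collapse = ", "))
  sel <- genome$genes[genome$genes$gene_id %in% gene_ids, , drop = FALSE]
  runs <- list()
  grp <- paste(sel$chromosome, sel$strand, sep = "\r")
  for (g in sort_c(unique(grp))) {
    part <- sel[grp == g, , drop = FALSE]
    part <- part[order(part$position), , drop = FALSE]
    n_strand <- sum(genome$genes$chromosome == part$chromosome[[1L]] &
                    genome$genes$strand == part$strand[[1L]])
    circ <- isTRUE(genome$circular[[part$chromosome[[1L]]]])
    if (nrow(part) == 1L) {
      runs[[length(runs) + 1L]] <- part
      next
    }
    gaps <- diff(part$position) - 1L
    breaks <- which(gaps > gap)
    if (circ) {
      wrap_gap <- n_strand - (max(part$position) - min(part$position)) - 1L
      if (wrap_gap <= gap && length(breaks) > 0L) {
        # rotate so that one linear break absorbs the wrap join
        cut <- breaks[[1L]]
        part <- rbind(part[seq(cut + 1L, nrow(part)), , drop = FALSE],
                      part[seq_len(cut), , drop = FALSE])
        gaps <- c(gaps[-cut], wrap_gap)
        breaks <- which(gaps > gap)
      } else if (wrap_gap <= gap && length(breaks) == 0L) {
        runs[[length(runs) + 1L]] <- part  # whole circle is one run
        next
      }
    }
    start <- 1L
    for (b in c(breaks, nrow(part))) {
      runs[[length(runs) + 1L]] <- part[seq(start, b), , drop = FALSE]
      start <- b + 1L
    }
  }
  runs
}

# Deterministic preference among candidate runs (ties by smallest
# chromosome/strand/position vector).
run_order_key <- function(run) {
  paste(run$chromosome[[1L]], run$strand[[1L]],
        paste(sprintf("%09d", sort(run$position)), collapse = ","))
}

# Genes of `genome` catalyzing at least one reaction of `rxns` under `corr`.
genes_for_reactions <- function(corr, rxns) {
  sort_c(unique(unlist(lapply(rxns, function(r) corr_genes(corr, r)),
                       use.names = FALSE)))
}

#' Largest neighbored subset of a reaction set in another species
#'
#' Given a reaction set of the reference species and the genome plus
#' correspondence of another species, returns a maximum-cardinality subset
#' whose reactions are catalyzed in that species by neighboring genes
#' (some qualifying gene per reaction; neighboring per
#' [genes_neighboring()]). Ties between equally large candidates are broken
#' toward the smallest gene-position vector.
#'
#' @param rset sorted character vector (a pooled reaction set).
#' @param genome the other species' [genome_table()].
#' @param corr the other species' [correspondence()].
#' @param gap neighbor gap (default 3).
#' @return Character vector, possibly empty; attribute `"genes"` holds the
#'   catalyzing genes of the chosen neighborhood.
#' @export
neighbored_reaction_subset <- function(rset, genome, corr, gap = 3L) {
  rset <- sort_c(unique(as.character(rset)))
  relevant <- genome$genes$gene_id[vapply(genome$genes$gene_id, function(g)
    FALSE, logical(1))]
  per_gene <- lapply(genome$genes$gene_id, function(g) character(0))
  names(per_gene) <- genome$genes$gene_id
  for (r in rset) {
    for (g in corr_genes(corr, r)) {
      if (!is.null(per_gene[[g]])) per_gene[[g]] <- c(per_gene[[g]], r)
    }
  }
  relevant <- names(per_gene)[lengths(per_gene) > 0L]
  if (length(relevant) == 0L)
    return(structure(character(0), genes = character(0)))
  runs <- neighbor_runs(genome, relevant, gap)
  best <- NULL; best_cov <- character(0); best_key <- NULL
  for (run in runs) {
    cov <- sort_c(unique(unlist(per_gene[run$gene_id], use.names = FALSE)))
    key <- run_order_key(run)
    if (is.null(best) || length(cov) > length(best_cov) ||
        (length(cov) == length(best_cov) &&
         sort(c(key, best_key), method = "radix")[[1L]] == key &&
         key != best_key)) {
      best <- run; best_cov <- cov; best_key <- key
    }
  }
  structure(best_cov, genes = sort_c(best$gene_id))
}

#' Species panel configuration
#'
#' Fixes the reference species, the column order of the remaining species
#' (the caller's ordering stands in for evolutionary distance), and the
#' neighbor gap used throughout grouping.
#'
#' @param reference reference species code.
#' @param species ordered character vector of the other panel species.
#' @param gap neighbor gap (default 3).
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(reference, species, gap = 3L) {
  reference <- as.character(reference)
  species <- as.character(species)
  if (reference %in% species)
    stop("reference species must not appear in the species column list")
  if (length(species) == 0L)
    stop("panel needs at least one species besides the reference")
  structure(list(reference = reference, species = species,
                 gap = as.integer(gap)),
            class = "panel_config")
}

# Validate pooled data: named list species -> list(genome, correspondence,
# records). Used by both grouping builders.
check_pooled <- function(panel, pooled) {
  need <- c(panel$reference, panel$species)
  missing <- setdiff(need, names(pooled))
  if (length(missing) > 0L)
    stop("missing species data for: ", paste(missing, collapse = ", "))
  invisible(NULL)
}

#' Species data bundle for grouping
#'
#' @param genome a [genome_table()].
#' @param correspondence a [correspondence()].
#' @param records trail-record data frame for the species (may be empty for
#'   non-reference species with no trails).
#' @return A list usable as one entry of the pooled data handed to
#'   [group_by_reactions()] / [group_by_genes()].
#' @export
species_data <- function(genome, correspondence, records = NULL) {
  if (is.null(records))
    records <- data.frame(species = character(0), pathway = character(0),
                          delta_d = integer(0), delta_g = integer(0),
                          reactions = character(0), span = integer(0),
                          genes = character(0), stringsAsFactors = FALSE)
  list(genome = genome, correspondence = correspondence, records = records)
}

# Order the reactions of a reference reaction set by the position of the
# reference genes catalyzing them (min position; ties by reaction id).
order_set_by_ref_genes <- function(rset, genome, corr) {
  pos <- vapply(rset, function(r) {
    gs <- corr_genes(corr, r)
    if (length(gs) == 0L) return(Inf)
    min(vapply(gs, function(g) {
      i <- match(g, genome$genes$gene_id)
      if (is.na(i)) Inf else as.numeric(genome$genes$position[[i]])
    }, numeric(1)))
  }, numeric(1))
  rset[order(pos, rset, method = "radix")]
}

#' Grouping table by reactions
#'
#' Builds the by-reactions conservation table of the reference species: one
#' row per (reaction set, reaction), one column per other panel species.
#' A cell holds `"x"` when the reaction belongs to the largest neighbored
#' subset of its row's reaction set in that species, `"."` when the species
#' performs the reaction outside that neighborhood, and `""` when the
#' species does not perform it at all.
#'
#' @param panel a [panel_config()].
#' @param pooled named list of [species_data()] bundles keyed by species
#'   code (reference included).
#' @return An object of class `grouping_table` (kind `"by_reactions"`).
#' @export
group_by_reactions <- function(panel, pooled) {
  check_pooled(panel, pooled)
  ref <- pooled[[panel$reference]]
  rsets <- pool_reaction_sets(ref$records)
  rows <- list()
  for (key in names(rsets)) {
    ordered <- order_set_by_ref_genes(rsets[[key]], ref$genome,
                                      ref$correspondence)
    rows[[length(rows) + 1L]] <-
      data.frame(set = key, reaction = ordered, stringsAsFactors = FALSE)
  }
  rows <- if (length(rows) > 0L) do.call(rbind, rows)
          else data.frame(set = character(0), reaction = character(0),
                          stringsAsFactors = FALSE)
  cells <- matrix("", nrow = nrow(rows), ncol = length(panel$species),
                  dimnames = list(NULL, panel$species))
  details <- list()
  for (sp in panel$species) {
    spd <- pooled[[sp]]
    for (key in names(rsets)) {
      sub <- neighbored_reaction_subset(rsets[[key]], spd$genome,
                                        spd$correspondence, panel$gap)
      details[[paste(key, sp, sep = "\r")]] <- sub
      idx <- which(rows$set == key)
      for (i in idx) {
        r <- rows$reaction[[i]]
        performed <- length(corr_genes(spd$correspondence, r)) > 0L
        cells[i, sp] <- if (r %in% sub) "x" else if (performed) "." else ""
      }
    }
  }
  structure(list(kind = "by_reactions", rows = rows, species = panel$species,
                 cells = cells, details = details),
            class = "grouping_table")
}

#' Grouping table by genes
#'
#' Builds the by-genes conservation table of the reference species. Rows are
#' the reference genes involved in reaction sets shared (as identical sets)
#' with at least one other panel species, ordered by chromosome, strand and
#' position. Rows fall into maximal neighboring gene groups; for each group
#' and each other species, the neighboring set of that species' functionally
#' similar genes maximizing the number of matched reference genes is chosen,
#' and those reference genes receive `"x"`, the rest of the group `"."`.
#'
#' @param panel a [panel_config()].
#' @param pooled named list of [species_data()] bundles keyed by species.
#' @return An object of class `grouping_table` (kind `"by_genes"`) whose
#'   `rows` carry chromosome, strand, position and gene; `details` records
#'   per (group, species) the chosen gene sets.
#' @export
group_by_genes <- function(panel, pooled) {
  check_pooled(panel, pooled)
  ref <- pooled[[panel$reference]]
  r_ref <- pool_reaction_sets(ref$records)
  other_keys <- unique(unlist(lapply(panel$species, function(sp)
    names(pool_reaction_sets(pooled[[sp]]$records))), use.names = FALSE))
  shared <- r_ref[names(r_ref) %in% other_keys]
  shared_rxns <- sort_c(unique(unlist(shared, use.names = FALSE)))
  gene_pool <- genes_for_reactions(ref$correspondence, shared_rxns)
  rows <- ref$genome$genes[ref$genome$genes$gene_id %in% gene_pool, ,
                           drop = FALSE]
  rows <- rows[order_c(rows$chromosome, rows$strand, rows$position), ,
               drop = FALSE]
  rownames(rows) <- NULL
  cells <- matrix(".", nrow = nrow(rows), ncol = length(panel$species),
                  dimnames = list(NULL, panel$species))
  details <- list()
  if (nrow(rows) > 0L) {
    groups <- neighbor_runs(ref$genome, rows$gene_id, panel$gap)
    for (gi in seq_along(groups)) {
      grp_genes <- groups[[gi]]$gene_id
      # reactions of shared sets catalyzed by genes of this group
      rr <- sort_c(unique(unlist(lapply(shared, function(rs)
        rs[vapply(rs, function(r)
          length(intersect(corr_genes(ref$correspondence, r),
                           grp_genes)) > 0L, logical(1))]),
        use.names = FALSE)))
      for (sp in panel$species) {
        spd <- pooled[[sp]]
        hh <- genes_for_reactions(spd$correspondence, rr)
        g_prime <- character(0); h_prime <- character(0)
        if (length(hh) > 0L) {
          best_key <- NULL
          for (run in neighbor_runs(spd$genome, hh, panel$gap)) {
            run_rxns <- rr[vapply(rr, function(r)
              length(intersect(corr_genes(spd$correspondence, r),
                               run$gene_id)) > 0L, logical(1))]
            cand <- grp_genes[vapply(grp_genes, function(g)
              any(vapply(run_rxns, function(r)
                g %in% corr_genes(ref$correspondence, r), logical(1))),
              logical(1))]
            key <- run_order_key(run)
            if (is.null(best_key) || length(cand) > length(g_prime) ||
                (length(cand) == length(g_prime) &&
                 sort(c(key, best_key), method = "radix")[[1L]] == key &&
                 key != best_key)) {
              g_prime <- cand; h_prime <- sort_c(run$gene_id)
              best_key <- key
            }
          }
        }
        details[[paste(gi, sp, sep = "\r")]] <-
          list(group = grp_genes, reactions = rr,
               h_prime = h_prime, g_prime = sort_c(g_prime))
        sel <- rows$gene_id %in% grp_genes
        cells[sel, sp] <- ifelse(rows$gene_id[sel] %in% g_prime, "x", ".")
      }
    }
  }
  structure(list(kind = "by_genes", rows = rows, species = panel$species,
                 cells = cells, details = details),
            class = "grouping_table")
}

#' @export
print.grouping_table <- function(x, ...) {
  cat("<grouping_table> ", x$kind, ": ", nrow(x$rows), " rows x ",
      length(x$species), " species\n", sep = "")
  invisible(x)
}

#' Write a grouping table as CSV
#'
#' RFC-4180 CSV with the row-label columns first (`set`, `reaction` for the
#' by-reactions table; `chromosome`, `strand`, `position`, `gene` for the
#' by-genes table) followed by one symbol column per species
#' (`"x"`, `"."`, `""`).
#'
#' @param table a `grouping_table`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_grouping_csv <- function(table, path) {
  stopifnot(inherits(table, "grouping_table"))
  labels <- if (table$kind == "by_genes") {
    data.frame(chromosome = table$rows$chromosome,
               strand = table$rows$strand,
               position = table$rows$position,
               gene = table$rows$gene_id, stringsAsFactors = FALSE)
  } else {
    table$rows
  }
  out <- cbind(labels, as.data.frame(table$cells, stringsAsFactors = FALSE,
                                     optional = TRUE))
  colnames(out) <- c(colnames(labels), table$species)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
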