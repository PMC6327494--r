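# Orchestration: per-species trail finding over a directory of pathways
# with gap expansion, timeout and blacklist handling, and the grouping
# entry point producing the two conservation CSVs.

#' Run configuration for trail finding
#'
#' @param species species code (used for provenance and the blacklist).
#' @param pathway_dir directory of pathway files; `.xml`/`.kgml` files are
#'   parsed as KGML, `.tsv` files as edge lists (their basename is the
#'   pathway id).
#' @param genome path to the species genome table TSV.
#' @param delta_d,delta_g gap parameters (defaults 0).
#' @param out output TSV of trail records.
#' @param timeout per-pathway wall-clock budget in seconds (default 300).
#' @param blacklist optional blacklist file path; timed-out pathways are
#'   appended and covered pathways skipped.
#' @return An object of class `run_config`.
#' @export
run_config <- function(species, pathway_dir, genome, delta_d = 0L,
                       delta_g = 0L, out = NULL, timeout = 300,
                       blacklist = NULL) {
  stopifnot(timeout > 0, delta_d >= 0, delta_g >= 0)
  structure(list(species = as.character(species),
                 pathway_dir = pathway_dir, genome = genome,
                 delta_d = as.integer(delta_d),
                 delta_g = as.integer(delta_g), out = out,
                 timeout = timeout, blacklist = blacklist),
            class = "run_config")
}

# id filter: KEGG-style ids go through pathway_filter; fixture ids that do
# not look like map identifiers are accepted as-is.
pathway_admissible <- function(id) {
  if (grepl("^[A-Za-z]{2,4}[0-9]{5}$", id)) pathway_filter(id) else TRUE
}

#' Trail finding over a pathway directory
#'
#' For each admissible, non-blacklisted pathway file: builds the model at
#' the configured gap parameters (gap-expanded reaction graph, gene graph,
#' derived reaction adjacency), solves every arc, and appends the surviving
#' trail records. A pathway that exhausts its timeout before producing any
#' record is appended to the blacklist and processing continues.
#'
#' @param config a [run_config()].
#' @return List with `records` (all trail records, deterministic order),
#'   `log` (data frame pathway/status with status in ok, blacklisted,
#'   skipped, filtered) and `out` (the results path, when written).
#' @export
run_trail_finding <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$genome))
    stop("genome table not found: ", config$genome)
  if (!dir.exists(config$pathway_dir))
    stop("pathway directory not found: ", config$pathway_dir)
  gt <- read_genome_table(config$genome)
  gene_graph <- build_gene_graph(gt$genome, config$delta_g)
  files <- sort_c(list.files(config$pathway_dir,
                             pattern = "\\.(xml|kgml|tsv)$",
                             full.names = TRUE))
  bl <- if (!is.null(config$blacklist)) read_blacklist(config$blacklist)
        else empty_blacklist()
  all_records <- list()
  log <- list()
  for (f in files) {
    id <- sub("\\.(xml|kgml|tsv)$", "", basename(f))
    status <- "ok"
    if (!pathway_admissible(id)) {
      log[[length(log) + 1L]] <- c(id, "filtered")
      next
    }
    if (blacklist_applies(bl, config$species, id, config$delta_d,
                          config$delta_g)) {
      log[[length(log) + 1L]] <- c(id, "skipped")
      next
    }
    if (grepl("\\.tsv$", f)) {
      D_raw <- read_pathway_tsv(f)
      corr <- gt$correspondence
    } else {
      parsed <- parse_kgml(f)
      D_raw <- parsed$pathway
      if (nzchar(parsed$id)) id <- parsed$id
      corr <- gt$correspondence
    }
    D <- expand_gaps_directed(D_raw, config$delta_d)
    G <- build_reaction_adjacency(D, gene_graph, corr)
    res <- solve_pathway(D, G, gene_graph, corr,
                         species = config$species, pathway = id,
                         delta_d = config$delta_d,
                         delta_g = config$delta_g,
                         timeout = config$timeout)
    if (res$blacklist) {
      status <- "blacklisted"
      bl <- rbind(bl, data.frame(species = config$species, pathway = id,
                                 delta_d = config$delta_d,
                                 delta_g = config$delta_g,
                                 stringsAsFactors = FALSE))
      if (!is.null(config$blacklist)) write_blacklist(bl, config$blacklist)
    } else if (nrow(res$records) > 0L) {
      all_records[[length(all_records) + 1L]] <- res$records
    }
    log[[length(log) + 1L]] <- c(id, status)
  }
  records <- if (length(all_records) > 0L) do.call(rbind, all_records)
             else solve_pathway(pathway_graph(), und_graph(),
                                und_graph(), correspondence())$records
  records <- records[order_c(records$pathway, -records$span,
                             records$reactions), , drop = FALSE]
  rownames(records) <- NULL
  if (!is.null(config$out)) write_trail_records(records, config$out)
  logdf <- if (length(log) > 0L)
    data.frame(pathway = vapply(log, `[[`, character(1), 1L),
               status = vapply(log, `[[`, character(1), 2L),
               stringsAsFactors = FALSE)
  else data.frame(pathway = character(0), status = character(0),
                  stringsAsFactors = FALSE)
  list(records = records, log = logdf, out = config$out)
}

#' Grouping over a results directory
#'
#' Builds the two conservation tables for a reference species from
#' per-species trail-record and genome files, and writes them as CSV. File
#' discovery is by species code: `<species>.tsv` under `results_dir` for
#' records and under `genome_dir` for genome tables. Parsed inputs can be
#' cached (plain in-memory parse stored per run) and reused by passing
#' `pooled` directly.
#'
#' @param panel a [panel_config()].
#' @param results_dir directory of per-species trail-record TSVs.
#' @param genome_dir directory of per-species genome-table TSVs.
#' @param out_dir output directory for the two CSVs.
#' @param pooled optional pre-parsed pooled data (as produced by a previous
#'   run, component `pooled` of the return value); when supplied the
#'   directories are not read.
#' @return List with `by_reactions`, `by_genes` (the tables), `files`
#'   (written CSV paths) and `pooled` (parsed inputs for reuse, e.g. when
#'   regrouping with another reference).
#' @export
run_grouping <- function(panel, results_dir = NULL, genome_dir = NULL,
                         out_dir = NULL, pooled = NULL) {
  stopifnot(inherits(panel, "panel_config"))
  species <- c(panel$reference, panel$species)
  if (is.null(pooled)) {
    pooled <- list()
    for (sp in species) {
      rf <- file.path(results_dir, paste0(sp, ".tsv"))
      gf <- file.path(genome_dir, paste0(sp, ".tsv"))
      if (!file.exists(gf))
        stop("missing genome table for species ", sp, ": ", gf)
      gt <- read_genome_table(gf)
      recs <- if (file.exists(rf)) read_trail_records(rf) else NULL
      if (sp == panel$reference &&
          (is.null(recs) || nrow(recs) == 0L))
        stop("no trail records for reference species ", sp)
      pooled[[sp]] <- species_data(gt$genome, gt$correspondence, recs)
    }
  }
  tr <- group_by_reactions(panel, pooled)
  tg <- group_by_genes(panel, pooled)
  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    f1 <- file.path(out_dir, paste0(panel$reference, "_by_reactions.csv"))
    f2 <- file.path(out_dir, paste0(panel$reference, "_by_genes.csv"))
    write_grouping_csv(tr, f1)
    write_grouping_csv(tg, f2)
    files <- c(f1, f2)
  }
  list(by_reactions = tr, by_genes = tg, files = files, pooled = pooled)
}
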