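# Readers and writers: KGML pathways, TSV genome tables and edge lists,
# trail-record TSV, the blacklist, and panel configuration files.

#' Parse a KGML pathway document
#'
#' Reads a KEGG Markup Language file into a [pathway_graph()] plus the
#' correspondence fragment carried by its gene entries. Every reaction
#' number named by a `<reaction>` element becomes a vertex; an arc runs from
#' one reaction to another when a compound the first can produce is a
#' compound the second can consume. Reversible reactions can run either
#' way, so their substrates and products both count as producible and as
#' consumable, which realises the cycles reversibility creates. Gene
#' entries (`<entry type="gene">`) attach their genes to the reactions they
#' name; the `org:` prefix on gene identifiers is stripped.
#'
#' @param path KGML file path (or anything [xml2::read_xml()] accepts).
#' @return List with components `pathway` (a [pathway_graph()]),
#'   `correspondence` (a [correspondence()]), `id` (e.g. `"eco00550"`) and
#'   `title`.
#' @export
parse_kgml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "pathway") stop("not a KGML document (root <", root, ">)")
  name <- xml2::xml_attr(doc, "name")
  id <- sub("^path:", "", ifelse(is.na(name), "", name))
  title <- xml2::xml_attr(doc, "title")

  strip_rn <- function(x) sub("^rn:", "", x)
  strip_org <- function(x) sub("^[A-Za-z0-9]+:", "", x)
  split_ws <- function(x) {
    if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character(0))
    strsplit(trimws(x), "[[:space:]]+")[[1L]]
  }

  producible <- list(); consumable <- list()
  for (rx in xml2::xml_find_all(doc, "./reaction")) {
    rns <- strip_rn(split_ws(xml2::xml_attr(rx, "name")))
    if (length(rns) == 0L) next
    rev <- identical(xml2::xml_attr(rx, "type"), "reversible")
    subs <- unlist(lapply(xml2::xml_find_all(rx, "./substrate"), function(s)
      split_ws(xml2::xml_attr(s, "name"))), use.names = FALSE)
    prods <- unlist(lapply(xml2::xml_find_all(rx, "./product"), function(p)
      split_ws(xml2::xml_attr(p, "name"))), use.names = FALSE)
    for (rn in rns) {
      # coerce through as.character: assigning NULL would drop the entry
      producible[[rn]] <- unique(as.character(c(producible[[rn]], prods,
                                                if (rev) subs)))
      consumable[[rn]] <- unique(as.character(c(consumable[[rn]], subs,
                                                if (rev) prods)))
    }
  }
  rxns <- sort_c(names(producible))
  arcs <- list()
  for (a in rxns) {
    for (b in rxns) {
      if (a == b) next
      if (length(intersect(producible[[a]], consumable[[b]])) > 0L)
        arcs[[length(arcs) + 1L]] <- c(a, b)
    }
  }
  arcs <- if (length(arcs) > 0L) do.call(rbind, arcs) else NULL
  D <- pathway_graph(arcs, vertices = rxns)

  mapping <- list()
  for (en in xml2::xml_find_all(doc, "./entry[@type='gene']")) {
    rns <- strip_rn(split_ws(xml2::xml_attr(en, "reaction")))
    genes <- strip_org(split_ws(xml2::xml_attr(en, "name")))
    for (rn in rns)
      mapping[[rn]] <- unique(c(mapping[[rn]], genes))
  }
  list(pathway = D, correspondence = correspondence(mapping),
       id = id, title = if (is.na(title)) "" else title)
}

#' Pathway identifier filter
#'
#' Keeps only maps of primary and secondary metabolism: global and overview
#' maps, whose five-digit number is 01100 or higher, are rejected.
#'
#' @param pathway_id identifier like `"eco00550"`.
#' @return `TRUE` when the numeric part is below 01100.
#' @export
pathway_filter <- function(pathway_id) {
  m <- regmatches(pathway_id,
                  regexec("^[A-Za-z]{2,4}([0-9]{5})$", pathway_id))[[1L]]
  if (length(m) != 2L)
    stop("cannot parse pathway id: ", pathway_id)
  as.integer(m[[2L]]) < 1100L
}

empty_blacklist <- function() {
  data.frame(species = character(0), pathway = character(0),
             delta_d = integer(0), delta_g = integer(0),
             stringsAsFactors = FALSE)
}

#' Read / write the pathway blacklist
#'
#' Plain-text store of pathways that timed out, one entry per line:
#' `species<TAB>pathway<TAB>delta_d<TAB>delta_g` (no header). A missing file
#' reads as an empty blacklist.
#'
#' @param path blacklist file.
#' @return `read_blacklist`: data frame with columns species, pathway,
#'   delta_d, delta_g.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) return(empty_blacklist())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blacklist())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L)
    stop("malformed blacklist line ", bad[[1L]], " in ", path)
  m <- do.call(rbind, parts)
  data.frame(species = m[, 1L], pathway = m[, 2L],
             delta_d = as.integer(m[, 3L]), delta_g = as.integer(m[, 4L]),
             stringsAsFactors = FALSE)
}

#' @rdname read_blacklist
#' @param blacklist data frame as returned by [read_blacklist()].
#' @export
write_blacklist <- function(blacklist, path) {
  lines <- sprintf("%s\t%s\t%d\t%d", blacklist$species, blacklist$pathway,
                   blacklist$delta_d, blacklist$delta_g)
  writeLines(lines, path)
  invisible(path)
}

#' Does the blacklist cover a query?
#'
#' A pathway blacklisted at some gap pair stays blacklisted for every
#' componentwise larger pair: a timeout can only get worse when more arcs
#' and edges are added.
#'
#' @param blacklist data frame from [read_blacklist()].
#' @param species,pathway query identifiers.
#' @param delta_d,delta_g queried gap parameters.
#' @return Logical scalar.
#' @export
blacklist_applies <- function(blacklist, species, pathway, delta_d, delta_g) {
  any(blacklist$species == species & blacklist$pathway == pathway &
      blacklist$delta_d <= delta_d & blacklist$delta_g <= delta_g)
}

#' Read / write a genome table
#'
#' Tab-separated genome tables with header columns `species`, `gene_id`,
#' `chromosome`, `strand` (`+`/`-`), `position`, `reactions`
#' (semicolon-separated reaction numbers, empty allowed). Reading returns
#' both the [genome_table()] and the [correspondence()] implied by the
#' reactions column.
#'
#' @param path TSV file.
#' @return `read_genome_table`: list with `genome` and `correspondence`.
#' @export
read_genome_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  req <- c("species", "gene_id", "chromosome", "strand", "position",
           "reactions")
  if (!all(req %in% names(df)))
    stop("genome table ", path, " must have columns: ",
         paste(req, collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0L)
    stop("invalid strand '", df$strand[[bad[[1L]]]], "' in ", path,
         " at row ", bad[[1L]])
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(pos) | pos < 0L)
  if (length(bad) > 0L)
    stop("invalid position in ", path, " at row ", bad[[1L]])
  species <- unique(df$species)
  if (length(species) != 1L)
    stop("genome table ", path, " must describe exactly one species")
  genome <- genome_table(species,
                         data.frame(gene_id = df$gene_id,
                                    chromosome = df$chromosome,
                                    strand = df$strand, position = pos,
                                    stringsAsFactors = FALSE))
  mapping <- list()
  for (i in seq_len(nrow(df))) {
    rxns <- strsplit(df$reactions[[i]], ";", fixed = TRUE)[[1L]]
    rxns <- rxns[nzchar(rxns)]
    for (r in rxns)
      mapping[[r]] <- c(mapping[[r]], df$gene_id[[i]])
  }
  list(genome = genome, correspondence = correspondence(mapping, genome))
}

#' @rdname read_genome_table
#' @param genome a [genome_table()].
#' @param corr a [correspondence()] for the same species.
#' @export
write_genome_table <- function(genome, corr, path) {
  genes <- genome$genes
  rxns <- vapply(genes$gene_id, function(g) {
    mine <- names(corr)[vapply(corr, function(gs) g %in% gs, logical(1))]
    paste(sort_c(mine), collapse = ";")
  }, character(1))
  df <- data.frame(species = genome$species, gene_id = genes$gene_id,
                   chromosome = genes$chromosome, strand = genes$strand,
                   position = genes$position, reactions = rxns,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a pathway edge list
#'
#' Minimal alternative to KGML: a TSV of arcs with header `from`, `to`.
#'
#' @param path TSV file.
#' @return `read_pathway_tsv`: a [pathway_graph()].
#' @export
read_pathway_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df)))
    stop("pathway edge list ", path, " must have columns from, to")
  pathway_graph(df[c("from", "to")])
}

#' @rdname read_pathway_tsv
#' @param D a [pathway_graph()].
#' @export
write_pathway_tsv <- function(D, path) {
  utils::write.table(data.frame(from = D$arcs[, 1L], to = D$arcs[, 2L],
                                stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write trail records
#'
#' TSV with header columns `species`, `pathway`, `delta_d`, `delta_g`,
#' `reactions` (semicolon-joined walk order), `span`, `genes`
#' (semicolon-joined genes backing the genomic consistency check).
#'
#' @param path TSV file.
#' @return `read_trail_records`: the records data frame.
#' @export
read_trail_records <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  req <- c("species", "pathway", "delta_d", "delta_g", "reactions", "span",
           "genes")
  if (!all(req %in% names(df)))
    stop("trail records ", path, " must have columns: ",
         paste(req, collapse = ", "))
  df$delta_d <- as.integer(df$delta_d)
  df$delta_g <- as.integer(df$delta_g)
  df$span <- as.integer(df$span)
  df[req]
}

#' @rdname read_trail_records
#' @param records trail-record data frame (see [solve_pathway()]).
#' @export
write_trail_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a panel configuration file
#'
#' YAML (or JSON, which YAML subsumes) with fields `reference`, `species`
#' (ordered list) and optional `gap`.
#'
#' @param path configuration file.
#' @return A [panel_config()].
#' @export
read_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$reference) || is.null(cfg$species))
    stop("panel config needs 'reference' and 'species'")
  panel_config(cfg$reference, unlist(cfg$species),
               gap = if (is.null(cfg$gap)) 3L else as.integer(cfg$gap))
}
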