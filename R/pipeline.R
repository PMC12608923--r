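#' Configure a full curation-to-classification run
#'
#' @param fasta path to the input FASTA (required).
#' @param hits optional path to a 12-column homology-hit table.
#' @param domains path to a 6-column domain-annotation table (required
#'   for motif regions and classification).
#' @param tree,taxa optional newick tree and tip-to-taxon map; when
#'   either is missing the tree-QC stage is skipped with a logged
#'   warning.
#' @param panel optional path to a labeled exemplar FASTA whose headers
#'   carry `label=` metadata... (see Details).
#' @param outdir output directory, created if needed.
#' @param mode `"reference"` or `"crustome"`: which hit filter to apply.
#' @param filter a [filter_config()].
#' @param params an [align_params()].
#' @param scheme a [similarity_scheme()].
#' @param k,m tree-QC settings (see [flag_long_branches()],
#'   [flag_taxon_inconsistency()]).
#' @param min_domains complete-domain minimum (see
#'   [filter_domain_completeness()]); `0` disables that stage.
#' @param identsim_ids ids to include in the identity/similarity matrix
#'   stage; `NULL` (default) computes it only when 40 or fewer sequences
#'   survive curation.
#'
#' @details The panel FASTA uses the same `key=value;` header dialect as
#' [read_fasta()] with an extra `label=` key per exemplar.
#'
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, domains, hits = NULL, tree = NULL,
                            taxa = NULL, panel = NULL, outdir = tempfile("run"),
                            mode = c("crustome", "reference"),
                            filter = filter_config(),
                            params = align_params(),
                            scheme = similarity_scheme(),
                            k = 5, m = 5L, min_domains = 0L,
                            identsim_ids = NULL) {
  mode <- match.arg(mode)
  for (p in c(fasta, domains, hits, tree, taxa, panel)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
  }
  structure(list(fasta = fasta, domains = domains, hits = hits,
                 tree = tree, taxa = taxa, panel = panel, outdir = outdir,
                 mode = mode, filter = filter, params = params,
                 scheme = scheme, k = k, m = m,
                 min_domains = as.integer(min_domains),
                 identsim_ids = identsim_ids),
            class = "pipeline_config")
}

#' Run the curation-to-classification pipeline
#'
#' Stages, in order: read inputs; hit filtering (reference or
#' transcriptome thresholds) when a hit table is given; complete-domain
#' filtering when `min_domains > 0`; tree QC (long branches +
#' taxon-inconsistency) when tree and taxa are given, otherwise skipped
#' with a warning; motif reports; family/subtype classification with
#' decapod names; an identity/similarity matrix over the surviving
#' sequences (when few enough, or as selected by `identsim_ids`). Every
#' stage writes a TSV under `outdir`, outputs are sorted by id, counts
#' reconcile at every stage, and a JSON + TSV run summary is written.
#'
#' @param config a [pipeline_config()].
#' @return the run summary (named list), invisibly; artifact files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = list(mode = config$mode,
                                min_domains = config$min_domains),
                  stages = list())

  records <- read_fasta(config$fasta)
  records <- records[order(records$id), , drop = FALSE]
  domains <- read_domain_table(config$domains, records)
  summary$stages$input <- list(n = nrow(records))

  kept <- records$id
  rejected_all <- list()
  if (!is.null(config$hits)) {
    hits <- read_hit_table(config$hits)
    qc <- if (config$mode == "reference") {
      filter_reference_hits(hits, domains, config$filter)
    } else {
      filter_crustome_hits(hits, config$filter)
    }
    # hit subjects absent from the FASTA are reported but not classified;
    # FASTA records without hits are dropped as unsupported
    kept <- intersect(kept, qc$kept)
    rejected_all$hit_filter <- qc$rejected
    write_tsv(qc$rejected[order(qc$rejected$id), , drop = FALSE],
              file.path(config$outdir, "qc_hit_filter.tsv"))
    summary$stages$hit_filter <- list(
      input = nrow(records), kept = length(kept),
      rejected = nrow(records) - length(kept),
      rejected_by_reason = as.list(table(qc$rejected$reason)))
  }
  if (config$min_domains > 0L) {
    sub <- records[records$id %in% kept, , drop = FALSE]
    qc <- filter_domain_completeness(sub, domains, config$min_domains)
    kept <- qc$kept
    rejected_all$domain_filter <- qc$rejected
    write_tsv(qc$rejected[order(qc$rejected$id), , drop = FALSE],
              file.path(config$outdir, "qc_domain_filter.tsv"))
    summary$stages$domain_filter <- list(
      input = nrow(sub), kept = length(kept),
      rejected = nrow(sub) - length(kept))
  }

  if (!is.null(config$tree) && !is.null(config$taxa)) {
    tree <- read_newick(config$tree)
    taxa <- read_taxa(config$taxa)
    long <- flag_long_branches(tree, k = config$k)
    incons <- flag_taxon_inconsistency(tree, taxa, m = config$m)
    write_tsv(long, file.path(config$outdir, "tree_qc_long_branches.tsv"))
    write_tsv(incons, file.path(config$outdir, "tree_qc_taxon.tsv"))
    summary$stages$tree_qc <- list(
      long_branches = nrow(long), taxon_inconsistent = nrow(incons))
  } else {
    warning("no tree/taxa supplied; tree-QC stage skipped")
    summary$stages$tree_qc <- "skipped"
  }

  surviving <- records[records$id %in% kept, , drop = FALSE]
  surviving <- surviving[order(surviving$id), , drop = FALSE]

  reports <- do.call(rbind, lapply(seq_len(nrow(surviving)), function(i) {
    suppressWarnings(motif_report(surviving[i, ], domains))
  }))
  if (is.null(reports)) reports <- motif_report("A")[0L, ]
  write_tsv(reports, file.path(config$outdir, "motif_report.tsv"))

  panel <- NULL
  if (!is.null(config$panel)) {
    praw <- read_fasta(config$panel)
    labels <- panel_labels(config$panel)
    panel <- reference_panel(praw, labels)
  }
  classes <- if (nrow(surviving) > 0L) {
    suppressWarnings(
      classify_dataset(surviving, domains, panel = panel,
                       params = config$params, scheme = config$scheme))
  } else {
    data.frame(seq_id = character(), species = character(),
               family = character(), subtype = character(),
               decapod_name = character(), confidence = character(),
               stringsAsFactors = FALSE)
  }
  write_tsv(classes, file.path(config$outdir, "classes.tsv"))
  summary$stages$classification <- list(
    n = nrow(classes), by_family = as.list(table(classes$family)))

  ids_for_matrix <- config$identsim_ids
  if (is.null(ids_for_matrix) && nrow(surviving) >= 2L &&
      nrow(surviving) <= 40L) {
    ids_for_matrix <- surviving$id
  }
  if (!is.null(ids_for_matrix) && length(ids_for_matrix) >= 2L) {
    sub <- surviving[surviving$id %in% ids_for_matrix, , drop = FALSE]
    mat <- identsim_matrix(sub, config$params, config$scheme)
    write_identsim_tsv(mat, file.path(config$outdir, "identsim.tsv"))
    summary$stages$identsim <- list(n = nrow(sub))
  } else {
    summary$stages$identsim <- "skipped"
  }

  tally <- tally_by_taxon(classes, setNames(surviving$phylum, surviving$id))
  write_tsv(as.data.frame.matrix(tally),
            file.path(config$outdir, "tally_by_taxon.tsv"))

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_tsv <- data.frame(
    stage = names(summary$stages),
    detail = vapply(summary$stages, function(s) {
      if (is.character(s)) s else paste(names(unlist(s)), unlist(s),
                                        sep = "=", collapse = "; ")
    }, character(1)), stringsAsFactors = FALSE)
  write_tsv(stage_tsv, file.path(config$outdir, "summary.tsv"))
  invisible(summary)
}

# labels for a panel FASTA: value of the label= key in each header
panel_labels <- function(path) {
  lines <- readLines(path)
  headers <- lines[startsWith(lines, ">")]
  vapply(headers, function(h) {
    m <- regmatches(h, regexec("label=([^;]+)", h))[[1L]]
    if (length(m) == 2L) trimws(m[2L]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Cross-tabulate classifications by phylum
#'
#' @param classifications a data.frame with columns `seq_id` and
#'   `family` (as from [classify_dataset()]).
#' @param taxon_map named character vector mapping seq id to phylum;
#'   ids without a taxon are counted under `"unknown"` with a warning.
#' @return a contingency `table` (phylum x family) with row/column
#'   totals; the grand total equals the number of classified sequences.
#' @export
tally_by_taxon <- function(classifications, taxon_map) {
  if (nrow(classifications) == 0L) {
    return(table(phylum = character(), family = character()))
  }
  phyla <- taxon_map[classifications$seq_id]
  if (any(is.na(phyla))) {
    warning(sum(is.na(phyla)), " sequence(s) without a taxon counted as 'unknown'")
    phyla[is.na(phyla)] <- "unknown"
  }
  stats::addmargins(table(phylum = phyla, family = classifications$family))
}
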