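#' Filtering thresholds for homology-hit curation
#'
#' Defaults follow the dataset-construction protocol: reference (NCBI)
#' hits are kept at e-value <= 1e-70, percent identity strictly above 60
#' and at least one complete conserved domain; transcriptome (CrusTome)
#' hits are kept at e-value <= 1e-120 with no identity or domain condition
#' at that stage; regulatory-subunit and PKC candidates additionally need
#' at least two complete conserved domains.
#'
#' @param reference_max_evalue inclusive e-value ceiling for reference hits.
#' @param reference_min_identity percent identity that must be strictly
#'   exceeded by a reference hit.
#' @param reference_min_domains minimum number of complete conserved
#'   domains for a reference subject.
#' @param crustome_max_evalue inclusive e-value ceiling for CrusTome hits.
#' @param min_complete_domains_r_pkc complete-domain minimum applied to
#'   PKA-R and PKC candidates by [filter_domain_completeness()].
#' @return a validated list of class `filter_config`.
#' @export
filter_config <- function(reference_max_evalue = 1e-70,
                          reference_min_identity = 60,
                          reference_min_domains = 1L,
                          crustome_max_evalue = 1e-120,
                          min_complete_domains_r_pkc = 2L) {
  cfg <- list(
    reference_max_evalue = reference_max_evalue,
    reference_min_identity = reference_min_identity,
    reference_min_domains = as.integer(reference_min_domains),
    crustome_max_evalue = crustome_max_evalue,
    min_complete_domains_r_pkc = as.integer(min_complete_domains_r_pkc)
  )
  stopifnot(is.finite(cfg$reference_max_evalue), cfg$reference_max_evalue > 0,
            is.finite(cfg$crustome_max_evalue), cfg$crustome_max_evalue > 0,
            cfg$reference_min_identity >= 0, cfg$reference_min_identity <= 100,
            cfg$reference_min_domains >= 0L,
            cfg$min_complete_domains_r_pkc >= 0L)
  class(cfg) <- "filter_config"
  cfg
}

qc_report <- function(kept, rejected) {
  if (nrow(rejected) == 0L) {
    rejected <- data.frame(id = character(), reason = character(),
                           detail = character(), stringsAsFactors = FALSE)
  }
  stopifnot(!anyDuplicated(c(kept, rejected$id)))
  structure(list(kept = kept, rejected = rejected), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: ", length(x$kept), " kept, ", nrow(x$rejected),
      " rejected\n", sep = "")
  if (nrow(x$rejected) > 0L) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

# best hit per subject: minimum e-value, maximum percent identity
best_hits_by_subject <- function(hits) {
  subjects <- sort(unique(hits$subject_id))
  data.frame(
    subject_id = subjects,
    best_evalue = vapply(subjects, function(s) {
      min(hits$evalue[hits$subject_id == s])
    }, numeric(1)),
    best_identity = vapply(subjects, function(s) {
      max(hits$percent_identity[hits$subject_id == s])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

count_complete_domains <- function(domains, ids) {
  vapply(ids, function(id) {
    sum(domains$seq_id == id & domains$complete)
  }, integer(1))
}

#' Filter reference homology hits
#'
#' A subject sequence is kept iff its best hit has e-value at or below
#' `cfg$reference_max_evalue` (inclusive), its best percent identity is
#' strictly above `cfg$reference_min_identity`, and it carries at least
#' `cfg$reference_min_domains` complete conserved-domain annotations.
#' Subjects with hits but no annotation row are rejected with reason
#' `domain_count` and detail `"no annotations"`. The kept and rejected
#' ids exactly partition the input subjects.
#'
#' @param hits a homology-hit table (see [read_hit_table()]).
#' @param domains a domain-annotation table keyed by `seq_id`.
#' @param cfg a [filter_config()].
#' @return a `qc_report`: list with `kept` (character vector) and
#'   `rejected` (data.frame `id`, `reason`, `detail`).
#' @export
filter_reference_hits <- function(hits, domains, cfg = filter_config()) {
  best <- best_hits_by_subject(hits)
  n_complete <- count_complete_domains(domains, best$subject_id)
  annotated <- best$subject_id %in% domains$seq_id
  kept <- character()
  rej <- list()
  for (i in seq_len(nrow(best))) {
    id <- best$subject_id[i]
    if (best$best_evalue[i] > cfg$reference_max_evalue) {
      rej[[id]] <- c("evalue", sprintf("best e-value %.3g > %.3g",
                                       best$best_evalue[i],
                                       cfg$reference_max_evalue))
    } else if (best$best_identity[i] <= cfg$reference_min_identity) {
      rej[[id]] <- c("identity", sprintf("best identity %.1f <= %.1f",
                                         best$best_identity[i],
                                         cfg$reference_min_identity))
    } else if (!annotated[i] && cfg$reference_min_domains > 0L) {
      rej[[id]] <- c("domain_count", "no annotations")
    } else if (n_complete[[i]] < cfg$reference_min_domains) {
      rej[[id]] <- c("domain_count", sprintf("%d complete domain(s) < %d",
                                             n_complete[[i]],
                                             cfg$reference_min_domains))
    } else {
      kept <- c(kept, id)
    }
  }
  qc_report(kept, rejection_frame(rej))
}

rejection_frame <- function(rej) {
  if (length(rej) == 0L) {
    return(data.frame(id = character(), reason = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  data.frame(id = names(rej),
             reason = vapply(rej, `[`, character(1), 1L),
             detail = vapply(rej, `[`, character(1), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter transcriptome (CrusTome) homology hits
#'
#' A subject is kept iff its best (minimum) e-value is at or below
#' `cfg$crustome_max_evalue`; the bound is inclusive, so an e-value of
#' exactly the threshold passes. No identity or domain condition applies
#' at this stage.
#'
#' @inheritParams filter_reference_hits
#' @return a `qc_report`.
#' @export
filter_crustome_hits <- function(hits, cfg = filter_config()) {
  best <- best_hits_by_subject(hits)
  keep <- best$best_evalue <= cfg$crustome_max_evalue
  rej <- best[!keep, , drop = FALSE]
  rejected <- data.frame(
    id = rej$subject_id, reason = rep("evalue", nrow(rej)),
    detail = sprintf("best e-value %.3g > %.3g", rej$best_evalue,
                     cfg$crustome_max_evalue),
    stringsAsFactors = FALSE
  )
  qc_report(best$subject_id[keep], rejected)
}

#' Filter sequences by complete conserved-domain count
#'
#' Used for PKA-R and PKC candidates, which must carry at least two
#' complete conserved domains to exclude unrelated proteins that share a
#' single domain (other cAMP-binding proteins, other kinases).
#'
#' @param records a sequence-record table.
#' @param domains a domain-annotation table.
#' @param min_domains minimum number of annotations with `complete = TRUE`.
#' @return a `qc_report` over `records$id`.
#' @export
filter_domain_completeness <- function(records, domains, min_domains = 2L) {
  stopifnot(min_domains >= 0L)
  n_complete <- count_complete_domains(domains, records$id)
  keep <- n_complete >= min_domains
  rejected <- data.frame(
    id = records$id[!keep], reason = rep("domain_count", sum(!keep)),
    detail = sprintf("%d complete domain(s) < %d", n_complete[!keep],
                     min_domains),
    stringsAsFactors = FALSE
  )
  qc_report(records$id[keep], rejected)
}

terminal_branch_lengths <- function(tree) {
  n_tip <- length(tree$tip.label)
  idx <- match(seq_len(n_tip), tree$edge[, 2L])
  setNames(tree$edge.length[idx], tree$tip.label)
}

#' Flag suspiciously long terminal branches
#'
#' A tip is flagged when its terminal branch length exceeds both
#' `k` times the median terminal length and the Tukey upper fence
#' (Q3 + 1.5 IQR) of terminal lengths. The dual condition avoids flagging
#' trees whose branches are uniformly long. Flags are returned sorted by
#' branch length, longest first.
#'
#' @param tree a `phylo` object with at least `min_tips` tips.
#' @param k multiple of the median terminal branch length that must be
#'   exceeded (default 5; `Inf` disables flagging).
#' @param min_tips minimum number of tips needed to estimate the null
#'   spread (default 10).
#' @return data.frame with columns `tip_id`, `branch_length`, `threshold`
#'   (the effective threshold, i.e. the larger of the two cutoffs).
#' @export
flag_long_branches <- function(tree, k = 5, min_tips = 10L) {
  n_tip <- length(tree$tip.label)
  if (n_tip < min_tips) {
    stop("tree has only ", n_tip, " tips (< ", min_tips,
         "); too few to estimate the null branch-length spread - review manually")
  }
  lens <- terminal_branch_lengths(tree)
  q <- quantile(lens, c(0.25, 0.75), names = FALSE)
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  cut_k <- k * median(lens)
  flagged <- lens[lens > cut_k & lens > fence]
  out <- data.frame(
    tip_id = names(flagged),
    branch_length = unname(flagged),
    threshold = rep(max(cut_k, fence), length(flagged)),
    stringsAsFactors = FALSE
  )
  out[order(-out$branch_length, out$tip_id), , drop = FALSE]
}

#' Flag tips whose tree neighborhood contradicts their taxon
#'
#' For each tip, the `m` nearest other tips by patristic distance are
#' collected (distance ties broken by tip id, lexicographically); the tip
#' is flagged when fewer than 2 of those neighbors share its phylum --
#' the signature of, e.g., an arthropod-labeled sequence nested inside a
#' nematode clade. With `m = 1` a tip can never reach 2 matching
#' neighbors and is always flagged; `m >= 3` is recommended.
#'
#' @param tree a `phylo` object.
#' @param taxon_map named character vector mapping every tip id to a
#'   phylum (see [read_taxa()]).
#' @param m neighborhood size (default 5).
#' @return data.frame with columns `tip_id`, `own_phylum`,
#'   `neighbor_phyla` (comma-separated, in distance order) and
#'   `n_same` (matching neighbors among the `m`).
#' @export
flag_taxon_inconsistency <- function(tree, taxon_map, m = 5L) {
  stopifnot(m >= 1L)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(taxon_map))
  if (length(missing) > 0L) {
    stop("no taxon for tip(s): ", paste(missing, collapse = ", "))
  }
  dmat <- ape::cophenetic.phylo(tree)
  out <- list()
  for (tip in tips) {
    others <- setdiff(tips, tip)
    d <- dmat[tip, others]
    ord <- others[order(d, others)]
    nb <- ord[seq_len(min(m, length(ord)))]
    own <- taxon_map[[tip]]
    n_same <- sum(taxon_map[nb] == own)
    if (n_same < 2L) {
      out[[tip]] <- data.frame(
        tip_id = tip, own_phylum = own,
        neighbor_phyla = paste(taxon_map[nb], collapse = ","),
        n_same = n_same, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tip_id = character(), own_phylum = character(),
                      neighbor_phyla = character(), n_same = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop gap-heavy alignment columns
#'
#' Plumbing for alignment clean-up before consensus or profiling: columns
#' whose gap fraction exceeds `max_gap_frac` are removed.
#'
#' @param alignment a named character vector of gapped rows.
#' @param max_gap_frac columns with a gap fraction strictly above this are
#'   dropped (default 0.9).
#' @return the trimmed alignment (named character vector).
#' @export
trim_alignment_gaps <- function(alignment, max_gap_frac = 0.9) {
  alignment <- as_alignment(alignment)
  mat <- alignment_matrix(alignment)
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_frac
  trimmed <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  setNames(trimmed, names(alignment))
}

# rows x columns character matrix view of an alignment
alignment_matrix <- function(alignment) {
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(mat) <- names(alignment)
  mat
}
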