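#' Build a labeled reference panel
#'
#' A reference panel is a sequence-record table with a `label` column
#' (family or family/subtype label per exemplar); it backs
#' [nearest_reference()] resolution of labels that architecture alone
#' cannot decide (novel PKC delta-like vs epsilon-like; RI_1 vs RI_D1).
#'
#' @param records a sequence-record table.
#' @param label character vector of labels, one per record.
#' @return the records with a `label` column, class `reference_panel`.
#' @export
reference_panel <- function(records, label) {
  validate_records(records)
  stopifnot(length(label) == nrow(records))
  records$label <- as.character(label)
  class(records) <- c("reference_panel", class(records))
  records
}

#' Label a sequence by its most similar reference exemplar
#'
#' Aligns the record against every exemplar with [global_align()] and
#' returns the label of the exemplar with maximal grouped similarity
#' (ties broken by maximal identity, then by lexicographically smaller
#' exemplar id; a tie is recorded in the result).
#'
#' @param record a sequence-record row.
#' @param panel a [reference_panel()].
#' @param params an [align_params()].
#' @param scheme a [similarity_scheme()].
#' @return list with `label`, `exemplar_id`, `identity`, `similarity`,
#'   `tie` (logical).
#' @export
nearest_reference <- function(record, panel, params = align_params(),
                              scheme = similarity_scheme()) {
  if (is.null(panel) || nrow(panel) == 0L) stop("empty reference panel")
  vals <- t(vapply(seq_len(nrow(panel)), function(i) {
    aln <- global_align(record, panel[i, ], params)
    ident_sim(aln, scheme)
  }, numeric(2)))
  ord <- order(-vals[, "similarity"], -vals[, "identity"], panel$id)
  best <- ord[1L]
  tie <- nrow(panel) > 1L &&
    vals[ord[2L], "similarity"] == vals[best, "similarity"] &&
    vals[ord[2L], "identity"] == vals[best, "identity"]
  list(label = panel$label[best], exemplar_id = panel$id[best],
       identity = unname(vals[best, "identity"]),
       similarity = unname(vals[best, "similarity"]), tie = tie)
}

domain_counts <- function(ann) {
  counts <- table(factor(ann$domain_name, levels = DOMAIN_VOCABULARY))
  as.list(counts)
}

check_contradictory_annotations <- function(ann) {
  if (nrow(ann) < 2L) return(invisible(NULL))
  for (i in seq_len(nrow(ann) - 1L)) {
    for (j in seq.int(i + 1L, nrow(ann))) {
      if (ann$domain_name[i] == ann$domain_name[j]) next
      ov <- min(ann$end[i], ann$end[j]) - max(ann$start[i], ann$start[j]) + 1L
      shorter <- min(ann$end[i] - ann$start[i], ann$end[j] - ann$start[j]) + 1L
      if (ov > 0.5 * shorter) {
        stop("contradictory annotations for '", ann$seq_id[1L], "': ",
             ann$domain_name[i], " ", ann$start[i], "-", ann$end[i],
             " overlaps ", ann$domain_name[j], " ", ann$start[j], "-",
             ann$end[j], " over more than half the shorter span")
      }
    }
  }
  invisible(NULL)
}

classification_result <- function(seq_id, family, subtype = NA_character_,
                                  evidence = list(), confidence = NA_character_,
                                  decapod_name = NA_character_) {
  ev <- if (length(evidence) == 0L) {
    data.frame(check = character(), outcome = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(check = names(evidence),
               outcome = unlist(evidence, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  structure(list(seq_id = seq_id, family = family, subtype = subtype,
                 decapod_name = decapod_name, evidence = ev,
                 confidence = confidence),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(x$seq_id, ": ", x$family,
      if (!is.na(x$subtype)) paste0(" / ", x$subtype),
      if (!is.na(x$decapod_name)) paste0(" [", x$decapod_name, "]"),
      " (", x$confidence, ")\n", sep = "")
  invisible(x)
}

#' Classify a sequence into a PKA/PKC family from its domain architecture
#'
#' The rule table is applied in a fixed order:
#' \enumerate{
#'   \item PKA-R: at least two cAMP-binding domains (a D/D domain is
#'     optional; truncated subunits lack one).
#'   \item PKN: at least one HR1 repeat plus a kinase domain (C2 optional).
#'   \item aPKC: PB1 + a single C1 + kinase.
#'   \item cPKC: C1 + C2 + kinase with C1 preceding C2.
#'   \item novel PKC: C2 preceding C1, plus kinase; delta-like vs
#'     epsilon-like is architecturally identical and resolved by
#'     [nearest_reference()] when a `panel` is given (family `"nPKC"`
#'     otherwise).
#'   \item PKA-C: a kinase domain only (no regulatory domains) plus
#'     N-terminal PKA motif evidence (anchored MGN motif, FxxxW, the MATL
#'     motif, or a glycine-rich N-terminal); kinase-only sequences
#'     without such evidence fall back to the panel, or `"unknown"`.
#' }
#' Overlapping annotations of different names sharing more than half the
#' shorter span are an error.
#'
#' @param record a sequence-record row.
#' @param annotations a domain-annotation table (at least one row for the
#'   record).
#' @param panel optional [reference_panel()] for nearest-reference
#'   resolution.
#' @param params,scheme alignment settings for the panel fallback.
#' @param novel_order domain-order constraint distinguishing novel from
#'   conventional PKCs: `"C2_first"` (default) means C2 precedes C1 in
#'   novel PKCs.
#' @return a `classification_result` (family, evidence, confidence).
#' @export
classify_family <- function(record, annotations, panel = NULL,
                            params = align_params(),
                            scheme = similarity_scheme(),
                            novel_order = c("C2_first", "C1_first")) {
  novel_order <- match.arg(novel_order)
  id <- record$id[1L]
  ann <- annotations[annotations$seq_id == id, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("no domain annotations for sequence '", id, "'")
  }
  check_contradictory_annotations(ann)
  n <- domain_counts(ann)
  first_start <- function(name) {
    s <- ann$start[ann$domain_name == name]
    if (length(s) == 0L) NA_integer_ else min(s)
  }
  evidence <- list(architecture = paste(
    sprintf("%s@%d-%d", ann$domain_name, ann$start, ann$end), collapse = " "))

  if (n$cAMP_binding >= 2L) {
    evidence$rule <- ">=2 cAMP-binding domains"
    evidence$dd <- if (n$DD >= 1L) "D/D present" else "no identifiable dimerization domain"
    return(classification_result(id, "PKA-R", evidence = evidence,
                                 confidence = "architecture_only"))
  }
  if (n$HR1 >= 1L && n$kinase >= 1L) {
    evidence$rule <- sprintf("%d HR1 repeat(s) + kinase", n$HR1)
    return(classification_result(id, "PKN", evidence = evidence,
                                 confidence = "architecture_only"))
  }
  if (n$PB1 >= 1L && n$C1 == 1L && n$kinase >= 1L && n$C2 == 0L) {
    evidence$rule <- "PB1 + single C1 + kinase"
    return(classification_result(id, "aPKC", evidence = evidence,
                                 confidence = "architecture_only"))
  }
  if (n$C1 >= 1L && n$C2 >= 1L && n$kinase >= 1L) {
    c1_first <- first_start("C1") < first_start("C2")
    conventional <- if (novel_order == "C2_first") c1_first else !c1_first
    if (conventional) {
      evidence$rule <- "C1 preceding C2 + kinase"
      return(classification_result(id, "cPKC", evidence = evidence,
                                   confidence = "architecture_only"))
    }
    evidence$rule <- "C2 preceding C1 + kinase (novel PKC)"
    if (!is.null(panel)) {
      sub_panel <- panel[panel$label %in% c("nPKC-delta-like",
                                            "nPKC-epsilon-like"), ,
                         drop = FALSE]
      if (nrow(sub_panel) > 0L) {
        nr <- nearest_reference(record, sub_panel, params, scheme)
        evidence$nearest_reference <- sprintf(
          "%s (%s, sim %.1f%%)", nr$label, nr$exemplar_id, nr$similarity)
        return(classification_result(id, nr$label, evidence = evidence,
                                     confidence = "architecture+motif"))
      }
    }
    return(classification_result(id, "nPKC", evidence = evidence,
                                 confidence = "architecture_only"))
  }
  regulatory <- n$C1 + n$C2 + n$PB1 + n$HR1 + n$cAMP_binding + n$DD
  if (n$kinase >= 1L && regulatory == 0L) {
    rep <- motif_report(record, annotations)
    gly <- is_gly_rich_nterm(record, annotations)
    motif_evidence <-
      rep$present[rep$check == "MGNxxxx[K/R]"] ||
      rep$present[rep$check == "MGNxxxxK"] ||
      rep$present[rep$check == "FxxxW"] ||
      rep$present[rep$check == "MATL[M/T/A]A[F/T]"] ||
      gly
    if (motif_evidence) {
      present <- rep$check[rep$present]
      if (gly) present <- c(present, "gly-rich N-terminal")
      evidence$rule <- "kinase only + N-terminal PKA motif evidence"
      evidence$motifs <- paste(present, collapse = ", ")
      return(classification_result(id, "PKA-C", evidence = evidence,
                                   confidence = "architecture+motif"))
    }
    if (!is.null(panel)) {
      nr <- nearest_reference(record, panel, params, scheme)
      evidence$rule <- "kinase only, no motif evidence"
      evidence$nearest_reference <- sprintf(
        "%s (%s, sim %.1f%%)", nr$label, nr$exemplar_id, nr$similarity)
      return(classification_result(id, nr$label, evidence = evidence,
                                   confidence = "nearest_reference_only"))
    }
  }
  classification_result(id, "unknown",
                        evidence = c(evidence,
                                     list(rule = "no architecture rule matched")),
                        confidence = "architecture_only")
}

#' Subtype a PKA catalytic subunit from its N-terminal features
#'
#' Priority when several signals fire: glycine-rich tract (`C_GLY`)
#' over the decapod `MATL[M/T/A]A[F/T]` motif (`C_D1`) over the anchored
#' ancestral `MGNxxxxK`/`MGNxxxx[K/R]` motif (`C_1`); a glycine tract is
#' the rarest and most specific signal. Sequences with none of these are
#' `"other-arthropod"`.
#'
#' @param record a sequence-record row (family PKA-C).
#' @param annotations a domain-annotation table.
#' @param report optional precomputed [motif_report()].
#' @param gly optional precomputed [is_gly_rich_nterm()] flag.
#' @param priority subtype priority order, most specific first.
#' @return one of `"C_GLY"`, `"C_D1"`, `"C_1"`, `"other-arthropod"`.
#' @export
classify_pka_c_isoform <- function(record, annotations, report = NULL,
                                   gly = NULL,
                                   priority = c("C_GLY", "C_D1", "C_1")) {
  if (is.null(report)) report <- motif_report(record, annotations)
  if (is.null(gly)) gly <- is_gly_rich_nterm(record, annotations)
  fired <- c(
    C_GLY = gly,
    C_D1 = report$present[report$check == "MATL[M/T/A]A[F/T]"],
    C_1 = report$present[report$check == "MGNxxxxK"] ||
      report$present[report$check == "MGNxxxx[K/R]"]
  )
  for (p in priority) {
    if (isTRUE(fired[[p]])) return(p)
  }
  "other-arthropod"
}

#' Subtype a PKA regulatory subunit
#'
#' Type I vs type II from the autoinhibitory site ([classify_ai_site()]):
#' `RRx[A/G]` alone gives RI, `RRxS` alone RII; both (at different
#' positions) give `"R-unresolved"` with both positions in the evidence,
#' as does neither. An RII subunit with a glycine-rich N-terminal is
#' `RII_GLY`. Absence of a D/D annotation is recorded in the evidence
#' (truncated subunit). When a `panel` with subtype-labeled exemplars
#' (`RI_1`, `RI_D1`, `RII_D1`, ...) is supplied, RI/RII calls are
#' refined by nearest reference.
#'
#' @param record a sequence-record row (family PKA-R).
#' @param annotations a domain-annotation table.
#' @param panel optional [reference_panel()] with subtype labels.
#' @param params,scheme alignment settings for the panel refinement.
#' @return list with `subtype` (e.g. `"RI"`, `"RII_GLY"`, `"RI_D1"`,
#'   `"R-unresolved"`), `ai` (the [classify_ai_site()] result), and
#'   `evidence` (data.frame of check/outcome pairs).
#' @export
classify_pka_r <- function(record, annotations, panel = NULL,
                           params = align_params(),
                           scheme = similarity_scheme()) {
  ai <- classify_ai_site(record, annotations = annotations)
  gly <- is_gly_rich_nterm(record, annotations)
  id <- record$id[1L]
  ann <- annotations[annotations$seq_id == id, , drop = FALSE]
  has_dd <- any(ann$domain_name == "DD")
  evidence <- list(
    ai_site = ai$class,
    dd = if (has_dd) "D/D present" else "no identifiable dimerization domain",
    gly_rich_nterm = as.character(gly)
  )
  if (ai$class == "ambiguous") {
    evidence$ri_positions <- paste(ai$ri_hits$start, collapse = ",")
    evidence$rii_positions <- paste(ai$rii_hits$start, collapse = ",")
  }
  subtype <- switch(ai$class,
                    RI = "RI",
                    RII = if (gly) "RII_GLY" else "RII",
                    "R-unresolved")
  confidence <- "architecture+motif"
  if (!is.null(panel) && subtype %in% c("RI", "RII")) {
    prefix <- paste0(subtype, "_")
    sub_panel <- panel[startsWith(panel$label, prefix), , drop = FALSE]
    if (nrow(sub_panel) > 0L) {
      nr <- nearest_reference(record, sub_panel, params, scheme)
      evidence$nearest_reference <- sprintf(
        "%s (%s, sim %.1f%%)", nr$label, nr$exemplar_id, nr$similarity)
      subtype <- nr$label
      confidence <- "nearest_reference_only"
    }
  }
  list(subtype = subtype, ai = ai, confidence = confidence,
       evidence = data.frame(check = names(evidence),
                             outcome = unlist(evidence, use.names = FALSE),
                             stringsAsFactors = FALSE))
}

#' Create an empty decapod-name registry
#'
#' The registry tracks, per species and isoform series, how many names
#' have been issued; ordinals are the order of characterization.
#'
#' @return an environment of class `name_registry`.
#' @export
create_registry <- function() {
  structure(new.env(parent = emptyenv()), class = "name_registry")
}

# series key: which naming sequence an isoform draws its ordinal from
naming_series <- function(family, subtype) {
  if (family == "PKA-C") {
    switch(subtype,
           C_1 = "PKA-C", C_GLY = "PKA-C_GLY", C_D1 = "PKA-C_D",
           NA_character_)
  } else if (family == "PKA-R") {
    switch(subtype,
           RI = "PKA-RI", RI_1 = "PKA-RI", RI_D1 = "PKA-RI_D",
           RII = "PKA-RII", RII_GLY = "PKA-RII_GLY", RII_D1 = "PKA-RII_D",
           NA_character_)
  } else {
    switch(family,
           cPKC = "cPKC_D", `nPKC-delta-like` = "nPKC_D.delta",
           `nPKC-epsilon-like` = "nPKC_D.epsilon", aPKC = "aPKC_D",
           PKN = "PKN_D", NA_character_)
  }
}

compose_name <- function(series, ordinal) {
  switch(series,
         "PKA-C" = sprintf("PKA-C_%d", ordinal),
         "PKA-C_GLY" = sprintf("PKA-C_GLY%d", ordinal),
         "PKA-C_D" = sprintf("PKA-C_D%d", ordinal),
         "PKA-RI" = sprintf("PKA-RI_%d", ordinal),
         "PKA-RI_D" = sprintf("PKA-RI_D%d", ordinal),
         "PKA-RII" = sprintf("PKA-RII_%d", ordinal),
         "PKA-RII_GLY" = if (ordinal == 1L) "PKA-RII_GLY"
                         else sprintf("PKA-RII_GLY%d", ordinal),
         "PKA-RII_D" = sprintf("PKA-RII_D%d", ordinal),
         "cPKC_D" = sprintf("cPKC_D%d", ordinal),
         "nPKC_D.delta" = sprintf("nPKC_D%d\u03b4", ordinal),
         "nPKC_D.epsilon" = sprintf("nPKC_D%d\u03b5", ordinal),
         "aPKC_D" = sprintf("aPKC_D%d", ordinal),
         "PKN_D" = sprintf("PKN_D%d", ordinal),
         NA_character_)
}

#' Issue a decapod isoform name
#'
#' Names follow the decapod nomenclature: subfamily prefix, `D` for
#' Decapoda, an ordinal equal to 1 + the number of isoforms of that
#' series already registered for the species (order of
#' characterization), with a Greek delta/epsilon suffix for novel PKCs
#' and a `GLY`/`GLYn` infix for glycine-rich isoforms. The registry is
#' updated in place, so repeated calls for one species never issue
#' duplicate names; the result is deterministic given input order.
#'
#' @param family a family label (e.g. `"cPKC"`, `"PKA-C"`, `"PKN"`).
#' @param subtype subtype string for PKA families (`"C_1"`, `"C_GLY"`,
#'   `"RI"`, `"RII_GLY"`, ...); ignored for PKC families.
#' @param species species the sequence belongs to.
#' @param registry a [create_registry()] environment.
#' @return the issued name (e.g. `"cPKC_D1"`, `"PKA-C_GLY2"`), or `NA`
#'   when the family/subtype has no naming series (e.g.
#'   `"other-arthropod"`).
#' @export
assign_decapod_name <- function(family, subtype = NA_character_, species,
                                registry) {
  if (family == "unknown") stop("cannot name an unknown-family sequence")
  series <- naming_series(family, subtype)
  if (is.na(series)) return(NA_character_)
  key <- paste(species, series, sep = "|")
  count <- if (exists(key, envir = registry, inherits = FALSE)) {
    get(key, envir = registry, inherits = FALSE)
  } else 0L
  ordinal <- count + 1L
  assign(key, ordinal, envir = registry)
  compose_name(series, ordinal)
}

#' Classify a whole dataset
#'
#' Runs [classify_family()] on every record, subtypes PKA-C and PKA-R
#' sequences, and (optionally) issues decapod names in input order.
#'
#' @param records a sequence-record table.
#' @param domains a domain-annotation table.
#' @param panel optional [reference_panel()].
#' @param params,scheme alignment settings.
#' @param name_isoforms issue decapod names (default `TRUE`).
#' @return data.frame with one row per record: `seq_id`, `species`,
#'   `family`, `subtype`, `decapod_name`, `confidence`; the per-sequence
#'   evidence tables are in `attr(, "evidence")`.
#' @export
classify_dataset <- function(records, domains, panel = NULL,
                             params = align_params(),
                             scheme = similarity_scheme(),
                             name_isoforms = TRUE) {
  validate_records(records)
  registry <- create_registry()
  rows <- vector("list", nrow(records))
  evidence <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    res <- classify_family(rec, domains, panel = panel, params = params,
                           scheme = scheme)
    subtype <- NA_character_
    confidence <- res$confidence
    if (res$family == "PKA-C") {
      subtype <- classify_pka_c_isoform(rec, domains)
    } else if (res$family == "PKA-R") {
      r <- classify_pka_r(rec, domains, panel = panel, params = params,
                          scheme = scheme)
      subtype <- r$subtype
      res$evidence <- rbind(res$evidence, r$evidence)
    }
    name <- NA_character_
    if (name_isoforms && res$family != "unknown" && res$family != "nPKC" &&
        !identical(subtype, "R-unresolved") &&
        !identical(subtype, "other-arthropod")) {
      name <- assign_decapod_name(res$family, subtype, rec$species, registry)
    }
    rows[[i]] <- data.frame(
      seq_id = rec$id, species = rec$species, family = res$family,
      subtype = subtype, decapod_name = name, confidence = confidence,
      stringsAsFactors = FALSE
    )
    evidence[[i]] <- res$evidence
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(evidence) <- out$seq_id
  attr(out, "evidence") <- evidence
  out
}
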