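#' Compile a degenerate protein motif
#'
#' The grammar has three tokens: an uppercase residue literal (one of the
#' 20 canonical amino acids), the wildcard `x` (any canonical residue;
#' the unknown residue `X` never matches), and a bracketed alternation
#' `[A/B]` or `[A/B/C]`. `"MGNxxxx[K/R]"` compiles to 8 positions with
#' position 8 = \{K, R\}.
#'
#' @param pattern motif string, e.g. `"FxxxW"` or `"MATL[M/T/A]A[F/T]"`.
#' @param anchored if `TRUE` the motif can only match starting at
#'   residue 1 of a sequence (used for N-terminal consensus motifs).
#' @return an object of class `degenerate_motif`: list with `pattern`,
#'   `positions` (list of allowed-residue sets) and `anchored`.
#' @examples
#' m <- compile_motif("MGNxxxx[K/R]", anchored = TRUE)
#' length(m$positions)  # 8
#' @export
compile_motif <- function(pattern, anchored = FALSE) {
  if (!nzchar(pattern)) stop("empty motif pattern")
  chars <- strsplit(pattern, "")[[1L]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == "x") {
      positions[[length(positions) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0L) {
        stop("unbalanced '[' at offset ", i, " in pattern '", pattern, "'")
      }
      close <- close[1L]
      inner <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      alts <- strsplit(inner, "/", fixed = TRUE)[[1L]]
      if (length(alts) == 0L || any(!nzchar(alts))) {
        stop("empty alternation at offset ", i, " in pattern '", pattern, "'")
      }
      if (any(!(alts %in% AA20))) {
        stop("invalid residue '", alts[!(alts %in% AA20)][1L],
             "' in alternation at offset ", i, " of pattern '", pattern, "'")
      }
      positions[[length(positions) + 1L]] <- alts
      i <- close + 1L
    } else {
      stop("invalid character '", ch, "' at offset ", i,
           " in pattern '", pattern, "'")
    }
  }
  structure(list(pattern = pattern, positions = positions,
                 anchored = anchored),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("degenerate motif '", x$pattern, "' (", length(x$positions),
      " positions", if (x$anchored) ", anchored", ")\n", sep = "")
  invisible(x)
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every match position left to right (overlaps included).
#' Anchored motifs return at most one hit, at residue 1. An `X` in the
#' sequence never matches any motif position, including the wildcard.
#'
#' @param record a sequence-record row (see [seq_records()]) or a plain
#'   amino-acid string.
#' @param motif a [compile_motif()] object, or a pattern string.
#' @param region optional `c(start, end)` (1-based inclusive) restricting
#'   the scan; hits must lie entirely inside it.
#' @return data.frame with columns `seq_id`, `pattern`, `start`, `end`,
#'   `match`; zero rows when there is no match.
#' @examples
#' find_motif("AFAAAWA", "FxxxW")  # hit at 2-6
#' @export
find_motif <- function(record, motif, region = NULL) {
  if (is.character(motif)) motif <- compile_motif(motif)
  seq <- if (is.data.frame(record)) record$residues[1L] else record
  id <- if (is.data.frame(record)) record$id[1L] else NA_character_
  n <- nchar(seq)
  if (is.null(region)) region <- c(1L, n)
  if (region[1L] < 1L || region[2L] > n || region[1L] > region[2L] + 1L) {
    stop("region ", region[1L], "-", region[2L],
         " outside sequence bounds (length ", n, ")")
  }
  m <- length(motif$positions)
  hits <- integer()
  if (region[2L] - region[1L] + 1L >= m) {
    chars <- strsplit(seq, "")[[1L]]
    starts <- if (motif$anchored) {
      if (region[1L] == 1L) 1L else integer()
    } else {
      seq.int(region[1L], region[2L] - m + 1L)
    }
    for (s in starts) {
      ok <- TRUE
      for (j in seq_len(m)) {
        if (!(chars[s + j - 1L] %in% motif$positions[[j]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  data.frame(
    seq_id = rep(id, length(hits)),
    pattern = rep(motif$pattern, length(hits)),
    start = hits, end = hits + m - 1L,
    match = if (length(hits) > 0L) substring(seq, hits, hits + m - 1L) else character(0),
    stringsAsFactors = FALSE
  )
}

#' N-terminal region of a sequence
#'
#' The N-terminal region runs from residue 1 to just before the first
#' core domain (kinase or cAMP-binding). When the first core domain
#' starts at residue 1 the region is empty (`end = 0`) and flagged with
#' attribute `empty = TRUE`.
#'
#' @param record a sequence-record row.
#' @param annotations a domain-annotation table containing at least one
#'   core-domain row for the record.
#' @return `c(start = 1, end)`; errors when no core-domain annotation
#'   exists for the sequence.
#' @export
nterm_region <- function(record, annotations) {
  id <- record$id[1L]
  core <- annotations[annotations$seq_id == id &
                        annotations$domain_name %in% CORE_DOMAINS, ,
                      drop = FALSE]
  if (nrow(core) == 0L) {
    stop("sequence '", id, "' has no kinase or cAMP-binding annotation; ",
         "supply domain annotations to define its N-terminal region")
  }
  end <- min(core$start) - 1L
  region <- c(start = 1L, end = end)
  if (end < 1L) attr(region, "empty") <- TRUE
  region
}

#' Type the autoinhibitory site of a PKA regulatory subunit
#'
#' The linker between the dimerization/docking (D/D) domain and the first
#' cAMP-binding domain carries the autoinhibitory site: a pseudosubstrate
#' `RRx[A/G]` in type I subunits and a phosphorylatable substrate `RRxS`
#' in type II. The region scanned defaults to that linker (D/D end + 1,
#' or residue 1 when no D/D is annotated, up to the first cAMP-binding
#' start - 1); without any cAMP-binding annotation the whole sequence is
#' scanned with a warning. Both motifs matching (at different positions)
#' yields `"ambiguous"`.
#'
#' @param record a sequence-record row or amino-acid string.
#' @param annotations optional domain-annotation table used to derive the
#'   linker region.
#' @param linker optional explicit `c(start, end)` region overriding the
#'   derivation.
#' @return list with `class` (`"RI"`, `"RII"`, `"ambiguous"` or
#'   `"none"`), `region`, and the hit tables `ri_hits` and `rii_hits`.
#' @examples
#' classify_ai_site("EIRRVSV")$class  # "RII"
#' @export
classify_ai_site <- function(record, annotations = NULL, linker = NULL) {
  seq <- if (is.data.frame(record)) record$residues[1L] else record
  id <- if (is.data.frame(record)) record$id[1L] else NA_character_
  n <- nchar(seq)
  if (is.null(linker)) {
    linker <- c(1L, n)
    if (!is.null(annotations)) {
      ann <- annotations[annotations$seq_id == id, , drop = FALSE]
      camp <- ann[ann$domain_name == "cAMP_binding", , drop = FALSE]
      dd <- ann[ann$domain_name == "DD", , drop = FALSE]
      if (nrow(camp) > 0L) {
        start <- if (nrow(dd) > 0L) max(dd$end) + 1L else 1L
        linker <- c(start, min(camp$start) - 1L)
      } else {
        warning("no cAMP-binding annotation for '", id,
                "'; scanning the whole sequence for the autoinhibitory site")
      }
    }
  }
  if (linker[1L] < 1L || linker[2L] > n) {
    stop("linker region ", linker[1L], "-", linker[2L],
         " outside sequence bounds (length ", n, ")")
  }
  ri <- find_motif(record, ai_motif_ri(), region = linker)
  rii <- find_motif(record, ai_motif_rii(), region = linker)
  cls <- if (nrow(ri) > 0L && nrow(rii) == 0L) "RI"
         else if (nrow(rii) > 0L && nrow(ri) == 0L) "RII"
         else if (nrow(ri) > 0L && nrow(rii) > 0L) "ambiguous"
         else "none"
  list(class = cls, region = linker, ri_hits = ri, rii_hits = rii)
}

ai_motif_ri <- function() compile_motif("RRx[A/G]")
ai_motif_rii <- function() compile_motif("RRxS")

#' Consensus string of a multiple sequence alignment
#'
#' Per column, over non-gap entries: the modal residue is emitted when its
#' frequency reaches `single_threshold`; otherwise the two most frequent
#' residues are emitted as `[A/B]` when they jointly reach
#' `pair_threshold` and each reaches 0.2; otherwise `x`. Columns that are
#' more than half gaps are emitted as `-`. Frequency ties are broken
#' alphabetically.
#'
#' @param alignment a named character vector of gapped rows.
#' @param single_threshold frequency needed to call a single residue
#'   (default 0.7; must be in (0.5, 1]).
#' @param pair_threshold joint frequency needed to call a two-residue
#'   alternation (default 0.7).
#' @return the consensus as a single string; attribute `"columns"` holds
#'   the per-column symbols (`"G"`, `"[K/R]"`, `"x"`, `"-"`).
#' @export
consensus <- function(alignment, single_threshold = 0.7,
                      pair_threshold = 0.7) {
  alignment <- as_alignment(alignment)
  stopifnot(single_threshold > 0.5, single_threshold <= 1,
            pair_threshold > 0.5, pair_threshold <= 1)
  mat <- alignment_matrix(alignment)
  cols <- apply(mat, 2L, function(col) {
    gap_frac <- mean(col == "-")
    if (gap_frac > 0.5) return("-")
    res <- col[col != "-"]
    freq <- sort(table(res), decreasing = TRUE)
    freq <- freq[order(-freq, names(freq))]
    p <- as.numeric(freq) / length(res)
    if (p[1L] >= single_threshold) return(names(freq)[1L])
    if (length(freq) >= 2L && p[1L] + p[2L] >= pair_threshold &&
        p[1L] >= 0.2 && p[2L] >= 0.2) {
      return(sprintf("[%s/%s]", names(freq)[1L], names(freq)[2L]))
    }
    "x"
  })
  structure(paste(cols, collapse = ""), columns = unname(cols))
}

#' Detect glycine-rich regions
#'
#' Slides a window over the search span and reports maximal regions
#' (overlapping qualifying windows merged) where the glycine fraction of
#' some window reaches `min_frac`. Defaults (window 25, fraction 0.4) are
#' calibrated so that the elongated glycine tracts of the crustacean GLY
#' isoforms qualify while ordinary N-termini do not.
#'
#' @param record a sequence-record row or amino-acid string.
#' @param window window length in residues (>= 5).
#' @param min_frac minimum glycine fraction within a window.
#' @param search_span optional `c(start, end)`; defaults to the
#'   N-terminal region when `annotations` are given, else the whole
#'   sequence.
#' @param annotations optional domain-annotation table (see
#'   [nterm_region()]).
#' @return data.frame with columns `seq_id`, `start`, `end`,
#'   `gly_fraction` (computed over the merged region) and `window`. A
#'   span shorter than the window yields zero rows with a warning and
#'   attribute `too_short = TRUE`.
#' @export
glycine_rich_regions <- function(record, window = 25L, min_frac = 0.4,
                                 search_span = NULL, annotations = NULL) {
  stopifnot(window >= 5L, min_frac > 0, min_frac <= 1)
  seq <- if (is.data.frame(record)) record$residues[1L] else record
  id <- if (is.data.frame(record)) record$id[1L] else NA_character_
  if (is.null(search_span)) {
    search_span <- if (!is.null(annotations) && is.data.frame(record)) {
      nterm_region(record, annotations)
    } else {
      c(1L, nchar(seq))
    }
  }
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), gly_fraction = numeric(),
                      window = integer(), stringsAsFactors = FALSE)
  span_len <- search_span[2L] - search_span[1L] + 1L
  if (span_len < window) {
    warning("search span (", max(span_len, 0L),
            " residues) shorter than the window (", window, ")")
    attr(empty, "too_short") <- TRUE
    return(empty)
  }
  chars <- strsplit(seq, "")[[1L]][search_span[1L]:search_span[2L]]
  is_g <- as.integer(chars == "G")
  csum <- c(0L, cumsum(is_g))
  starts_rel <- seq_len(span_len - window + 1L)
  frac <- (csum[starts_rel + window] - csum[starts_rel]) / window
  ok <- which(frac >= min_frac)
  if (length(ok) == 0L) return(empty)
  # merge overlapping/adjacent qualifying windows into maximal regions
  runs <- split(ok, cumsum(c(1L, diff(ok) > window)))
  out <- lapply(runs, function(r) {
    s_rel <- min(r)
    e_rel <- max(r) + window - 1L
    g <- csum[e_rel + 1L] - csum[s_rel]
    data.frame(seq_id = id,
               start = search_span[1L] + s_rel - 1L,
               end = search_span[1L] + e_rel - 1L,
               gly_fraction = g / (e_rel - s_rel + 1L),
               window = window, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Is the N-terminal region glycine-rich?
#'
#' @inheritParams glycine_rich_regions
#' @param annotations domain-annotation table defining the N-terminal
#'   region (see [nterm_region()]).
#' @return `TRUE` iff at least one glycine-rich region is found within
#'   the N-terminal region.
#' @export
is_gly_rich_nterm <- function(record, annotations, window = 25L,
                              min_frac = 0.4) {
  span <- nterm_region(record, annotations)
  if (isTRUE(attr(span, "empty")) || span[2L] - span[1L] + 1L < window) {
    return(FALSE)
  }
  regions <- glycine_rich_regions(record, window = window,
                                  min_frac = min_frac, search_span = span)
  nrow(regions) > 0L
}

# the standard motif checks run by motif_report()
MOTIF_CHECKS <- list(
  list(name = "MGNxxxx[K/R]", pattern = "MGNxxxx[K/R]", anchored = TRUE,  where = "seq"),
  list(name = "MGNxxxxK",     pattern = "MGNxxxxK",     anchored = TRUE,  where = "seq"),
  list(name = "FxxxW",        pattern = "FxxxW",        anchored = FALSE, where = "nterm"),
  list(name = "MATL[M/T/A]A[F/T]", pattern = "MATL[M/T/A]A[F/T]",
       anchored = FALSE, where = "nterm"),
  list(name = "IxI",          pattern = "IxI",          anchored = FALSE, where = "nterm"),
  list(name = "VxV",          pattern = "VxV",          anchored = FALSE, where = "nterm"),
  list(name = "RRx[A/G]",     pattern = "RRx[A/G]",     anchored = FALSE, where = "linker"),
  list(name = "RRxS",         pattern = "RRxS",         anchored = FALSE, where = "linker")
)

#' Run the standard N-terminal motif checks on one sequence
#'
#' Scans for the eight diagnostic patterns (anchored `MGNxxxx[K/R]` and
#' `MGNxxxxK`; `FxxxW`; `MATL[M/T/A]A[F/T]`; the AKAP-binding `IxI` and
#' `VxV`; the autoinhibitory `RRx[A/G]` and `RRxS`) plus the G2
#' myristoylation site (glycine at residue 2). When `annotations` are
#' supplied, N-terminal patterns are restricted to the N-terminal region
#' and the autoinhibitory patterns to the D/D-to-cAMP linker; otherwise
#' the whole sequence is scanned.
#'
#' @param record a sequence-record row or amino-acid string.
#' @param annotations optional domain-annotation table.
#' @return data.frame with one row per check: `seq_id`, `check`,
#'   `present`, `start`, `end`, `match` (first hit; NA when absent).
#' @export
motif_report <- function(record, annotations = NULL) {
  seq <- if (is.data.frame(record)) record$residues[1L] else record
  id <- if (is.data.frame(record)) record$id[1L] else NA_character_
  n <- nchar(seq)
  nterm <- c(1L, n)
  linker <- NULL  # NULL = whole sequence via classify_ai_site fallback
  if (!is.null(annotations) && is.data.frame(record)) {
    ann <- annotations[annotations$seq_id == id, , drop = FALSE]
    if (any(ann$domain_name %in% CORE_DOMAINS)) {
      span <- nterm_region(record, annotations)
      if (!isTRUE(attr(span, "empty"))) nterm <- unname(span)
    }
  }
  rows <- list()
  for (chk in MOTIF_CHECKS) {
    motif <- compile_motif(chk$pattern, anchored = chk$anchored)
    region <- switch(chk$where,
                     seq = c(1L, n),
                     nterm = nterm,
                     linker = NULL)
    hits <- if (chk$where == "linker") {
      ai <- suppressWarnings(classify_ai_site(record, annotations = annotations))
      if (chk$pattern == "RRx[A/G]") ai$ri_hits else ai$rii_hits
    } else if (region[2L] >= region[1L]) {
      find_motif(record, motif, region = region)
    } else {
      find_motif(record, motif, region = c(1L, n))[0L, ]
    }
    rows[[chk$name]] <- data.frame(
      seq_id = id, check = chk$name, present = nrow(hits) > 0L,
      start = if (nrow(hits) > 0L) hits$start[1L] else NA_integer_,
      end = if (nrow(hits) > 0L) hits$end[1L] else NA_integer_,
      match = if (nrow(hits) > 0L) hits$match[1L] else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  g2 <- n >= 2L && substr(seq, 2L, 2L) == "G"
  rows[["G2"]] <- data.frame(
    seq_id = id, check = "G2", present = g2,
    start = if (g2) 2L else NA_integer_, end = if (g2) 2L else NA_integer_,
    match = if (g2) "G" else NA_character_, stringsAsFactors = FALSE
  )
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
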