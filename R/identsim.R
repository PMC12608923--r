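#' Amino-acid similarity groups
#'
#' The grouped-similarity scheme: two aligned residues are "similar" when
#' they are identical or belong to the same physicochemical group. The
#' default groups are GAVLI, FYW, CM, ST, KRH, DENQ and P; they are
#' pairwise disjoint and cover the 20 canonical residues. The unknown
#' residue `X` belongs to no group and is never similar, not even to
#' itself.
#'
#' @param groups list of character vectors of residues.
#' @return object of class `similarity_scheme`: list with `groups` and
#'   `group_of` (named vector mapping residue to group index).
#' @export
similarity_scheme <- function(groups = list(
  c("G", "A", "V", "L", "I"),
  c("F", "Y", "W"),
  c("C", "M"),
  c("S", "T"),
  c("K", "R", "H"),
  c("D", "E", "N", "Q"),
  "P"
)) {
  all_res <- unlist(groups)
  if (anyDuplicated(all_res)) {
    stop("similarity groups must be pairwise disjoint")
  }
  if (!setequal(all_res, AA20)) {
    stop("similarity groups must cover exactly the 20 canonical residues")
  }
  group_of <- integer(0)
  for (g in seq_along(groups)) {
    group_of[groups[[g]]] <- g
  }
  structure(list(groups = groups, group_of = group_of),
            class = "similarity_scheme")
}

#' Global pairwise alignment parameters
#'
#' @param matrix substitution matrix name (a matrix shipped with
#'   Biostrings, default `"BLOSUM62"`).
#' @param gap_open gap opening penalty (positive; default 10).
#' @param gap_extend gap extension penalty (positive, at most
#'   `gap_open`; default 0.5). A gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param terminal_gaps if `TRUE` (default) terminal gaps are penalized
#'   (plain global alignment); if `FALSE`, ends-free alignment is used.
#' @return object of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, terminal_gaps = TRUE) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, terminal_gaps = terminal_gaps),
            class = "align_params")
}

substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, scored
#' with the substitution matrix in `params`. The dynamic program is
#' delegated to [Biostrings::pairwiseAlignment()]; the score convention
#' is `sum of matrix scores - sum over gaps of (gap_open + length *
#' gap_extend)`.
#'
#' @param a,b sequence-record rows or plain amino-acid strings.
#' @param params an [align_params()] object.
#' @return object of class `pairwise_alignment`: list with `a_id`,
#'   `b_id`, `a_aln`, `b_aln` (gapped rows of equal length) and `score`.
#' @examples
#' aln <- global_align("ACDEF", "ACEF")
#' aln$score
#' @export
global_align <- function(a, b, params = align_params()) {
  seq_a <- if (is.data.frame(a)) a$residues[1L] else a
  seq_b <- if (is.data.frame(b)) b$residues[1L] else b
  id_a <- if (is.data.frame(a)) a$id[1L] else "a"
  id_b <- if (is.data.frame(b)) b$id[1L] else "b"
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("cannot align an empty sequence")
  if (!grepl(sprintf("[%s]", paste(AA20, collapse = "")), seq_a)) {
    stop("sequence '", id_a, "' contains only unknown (X) residues; unalignable")
  }
  if (!grepl(sprintf("[%s]", paste(AA20, collapse = "")), seq_b)) {
    stop("sequence '", id_b, "' contains only unknown (X) residues; unalignable")
  }
  type <- if (params$terminal_gaps) "global" else "overlap"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = substitution_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = type
  )
  out <- list(
    a_id = id_a, b_id = id_b,
    a_aln = as.character(Biostrings::alignedPattern(pa)),
    b_aln = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise alignment ", x$a_id, " vs ", x$b_id,
      " (", nchar(x$a_aln), " columns, score ", format(x$score), ")\n",
      sep = "")
  invisible(x)
}

#' Grouped percent identity and similarity of a pairwise alignment
#'
#' Identity is the percentage of alignment columns where both residues
#' are equal; similarity additionally counts columns whose residues fall
#' in the same physicochemical group of `scheme`. Gap-vs-residue columns
#' are neither identical nor similar; the unknown residue `X` counts as
#' mismatch even against itself. With `denominator = "alignment"`
#' (default) the denominator is the full column count, gap columns
#' included; with `"shorter"` it is the length of the shorter (degapped)
#' sequence. Values are returned at full precision; round at the
#' reporting layer.
#'
#' @param aln a `pairwise_alignment` (see [global_align()]), or any list
#'   with gapped rows `a_aln` and `b_aln`.
#' @param scheme a [similarity_scheme()].
#' @param denominator `"alignment"` or `"shorter"`.
#' @return named numeric vector `c(identity = , similarity = )`, in
#'   percent.
#' @examples
#' aln <- list(a_aln = "MGNAAAK", b_aln = "MGNAGIK")
#' ident_sim(aln)  # identity 5/7, similarity 7/7
#' @export
ident_sim <- function(aln, scheme = similarity_scheme(),
                      denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  ra <- strsplit(aln$a_aln, "")[[1L]]
  rb <- strsplit(aln$b_aln, "")[[1L]]
  if (length(ra) != length(rb)) stop("alignment rows differ in length")
  if (any(ra == "-" & rb == "-")) stop("alignment has a gap-in-both column")
  canonical <- ra %in% AA20 & rb %in% AA20
  identical_col <- canonical & ra == rb
  ga <- scheme$group_of[ra]
  gb <- scheme$group_of[rb]
  similar_col <- identical_col | (canonical & !is.na(ga) & !is.na(gb) & ga == gb)
  d <- switch(denominator,
              alignment = length(ra),
              shorter = min(sum(ra != "-"), sum(rb != "-")))
  c(identity = 100 * sum(identical_col) / d,
    similarity = 100 * sum(similar_col) / d)
}

#' Pairwise identity/similarity matrix
#'
#' Aligns every unordered pair once with [global_align()], computes the
#' grouped statistic with [ident_sim()] and mirrors it into symmetric
#' matrices with an exact 100/100 diagonal. A shading bin (1 = least to
#' 4 = most similar) is assigned per matrix by min-max scaling of the
#' off-diagonal values.
#'
#' @param records a sequence-record table with at least two rows and
#'   unique ids.
#' @param params an [align_params()].
#' @param scheme a [similarity_scheme()].
#' @param denominator passed to [ident_sim()].
#' @return object of class `identsim_matrix`: list with `ids`,
#'   `identity`, `similarity` (numeric matrices, percent), and
#'   `shading_identity` / `shading_similarity` (integer bin matrices).
#' @export
identsim_matrix <- function(records, params = align_params(),
                            scheme = similarity_scheme(),
                            denominator = "alignment") {
  validate_records(records)
  if (nrow(records) < 2L) stop("need at least 2 records")
  ids <- records$id
  n <- length(ids)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  smm <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- global_align(records[i, ], records[j, ], params)
      v <- ident_sim(aln, scheme, denominator)
      idm[i, j] <- idm[j, i] <- v[["identity"]]
      smm[i, j] <- smm[j, i] <- v[["similarity"]]
    }
  }
  structure(list(ids = ids, identity = idm, similarity = smm,
                 shading_identity = shading_bins(idm),
                 shading_similarity = shading_bins(smm)),
            class = "identsim_matrix")
}

# min-max scale off-diagonal values and bin into quarters (1 low .. 4 high)
shading_bins <- function(m) {
  off <- m[row(m) != col(m)]
  rng <- range(off)
  scaled <- if (diff(rng) == 0) {
    matrix(1, nrow(m), ncol(m))
  } else {
    (m - rng[1L]) / diff(rng)
  }
  bins <- pmin(floor(scaled * 4) + 1L, 4L)
  diag(bins) <- NA_integer_
  dimnames(bins) <- dimnames(m)
  bins
}

#' @export
print.identsim_matrix <- function(x, digits = 1, ...) {
  cat("identity (upper) / similarity (lower) matrix over ",
      length(x$ids), " sequences\n", sep = "")
  print(round(combined_identsim(x), digits))
  invisible(x)
}

# identity above the diagonal, similarity below, 100 on the diagonal
combined_identsim <- function(x) {
  m <- x$identity
  m[lower.tri(m)] <- x$similarity[lower.tri(m)]
  m
}

#' Write an identity/similarity matrix as TSV
#'
#' Mirrors the conventional table layout: percent identity above the
#' diagonal, percent similarity below, 100 on the diagonal; values
#' rounded to one decimal.
#'
#' @param x an `identsim_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_identsim_tsv <- function(x, path) {
  m <- round(combined_identsim(x), 1)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Per-column conservation profile of an MSA against a reference row
#'
#' For each alignment column, the percentage of rows whose residue equals
#' the reference row's residue is computed (the reference row counts in
#' both numerator and denominator), optionally smoothed with a centered
#' sliding-window mean, and assigned to strict conservation bins:
#' `>80`, `>60`, `>40`, `<=40`. Columns where the reference row has a gap
#' are undefined (`NA` percent, bin `"undefined"`).
#'
#' @param alignment a named character vector of gapped rows.
#' @param reference_row the name of the reference row.
#' @param window sliding-window length (odd, default 1 = no smoothing).
#' @return data.frame with columns `column`, `percent`, `bin`.
#' @export
msa_identity_profile <- function(alignment, reference_row, window = 1L) {
  alignment <- as_alignment(alignment)
  stopifnot(window >= 1L)
  if (!(reference_row %in% names(alignment))) {
    stop("reference row '", reference_row, "' not found in the alignment")
  }
  mat <- alignment_matrix(alignment)
  ref <- mat[reference_row, ]
  pct <- vapply(seq_len(ncol(mat)), function(j) {
    if (ref[j] == "-") return(NA_real_)
    100 * mean(mat[, j] == ref[j])
  }, numeric(1))
  if (window > 1L) {
    half <- (window - 1L) %/% 2L
    sm <- vapply(seq_along(pct), function(j) {
      idx <- max(1L, j - half):min(length(pct), j + half)
      if (is.na(pct[j])) NA_real_ else mean(pct[idx], na.rm = TRUE)
    }, numeric(1))
    pct <- sm
  }
  bin <- ifelse(is.na(pct), "undefined",
                ifelse(pct > 80, ">80",
                       ifelse(pct > 60, ">60",
                              ifelse(pct > 40, ">40", "<=40"))))
  data.frame(column = seq_along(pct), percent = pct, bin = bin,
             stringsAsFactors = FALSE)
}
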