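#' Construct a table of protein sequence records
#'
#' The package's sequence container is a plain `data.frame` with one row per
#' protein and columns `id`, `species`, `phylum`, `residues` and `source`.
#' `seq_records()` builds and validates one from vectors; [validate_records()]
#' checks an existing data frame.
#'
#' @param id character vector of unique, non-empty sequence identifiers.
#' @param residues character vector of amino-acid strings over the 20
#'   canonical residues plus `X` (lowercase input is uppercased).
#' @param species,phylum optional taxonomy; default `"unknown"`.
#' @param source provenance of the sequences: `"reference"`, `"crustome"`
#'   or `"synthetic"`.
#' @return A `data.frame` with columns `id`, `species`, `phylum`,
#'   `residues`, `source`.
#' @examples
#' seq_records("s1", "MGNAAATKGSE", species = "Carcinus maenas",
#'             phylum = "Arthropoda")
#' @export
seq_records <- function(id, residues, species = "unknown",
                        phylum = "unknown", source = "reference") {
  df <- data.frame(
    id = as.character(id),
    species = rep_len(as.character(species), length(id)),
    phylum = rep_len(as.character(phylum), length(id)),
    residues = toupper(as.character(residues)),
    source = rep_len(as.character(source), length(id)),
    stringsAsFactors = FALSE
  )
  validate_records(df)
}

#' Validate a sequence-record table
#'
#' @param records a data.frame as returned by [seq_records()].
#' @return `records`, invisibly unchanged, or an error describing the first
#'   violated invariant (duplicate or empty id, empty sequence, residue
#'   outside the amino-acid alphabet, with its position).
#' @export
validate_records <- function(records) {
  required <- c("id", "species", "phylum", "residues", "source")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("sequence table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!nzchar(records$id))) stop("empty sequence id")
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(records$residues) < 1L)) {
    bad <- records$id[nchar(records$residues) < 1L][1L]
    stop("sequence '", bad, "' is empty")
  }
  bad_pos <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET_OK, collapse = "")),
                     records$residues)
  if (any(bad_pos > 0L)) {
    i <- which(bad_pos > 0L)[1L]
    stop("sequence '", records$id[i], "' has a non-amino-acid character '",
         substr(records$residues[i], bad_pos[i], bad_pos[i]),
         "' at position ", bad_pos[i])
  }
  records
}

#' Sequence lengths of a record table
#' @param records a sequence-record table.
#' @return named integer vector of residue counts.
#' @export
record_lengths <- function(records) {
  setNames(nchar(records$residues), records$id)
}

# fetch one record row by id, with a clear error
get_record <- function(records, id) {
  i <- match(id, records$id)
  if (is.na(i)) stop("no sequence with id '", id, "'")
  records[i, , drop = FALSE]
}
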