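#' Read protein sequences from a FASTA file
#'
#' Headers may carry taxonomy after the first whitespace as
#' `key=value; key=value` pairs (recognized keys: `species`, `phylum`,
#' `source`); anything unrecognized is ignored and the corresponding
#' fields default to `"unknown"` (or the `source` argument). Wrapped
#' sequence lines are concatenated and lowercase residues uppercased.
#'
#' @param path path to a FASTA file.
#' @param source default provenance for records whose header carries no
#'   `source=` key.
#' @return A sequence-record `data.frame` (see [seq_records()]); an empty
#'   file yields a zero-row table.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 species=Carcinus maenas; phylum=Arthropoda",
#'              "MGNAAATKGSE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, source = "reference") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(seq_records(character(), character())[0L, ])
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  meta <- lapply(headers, parse_fasta_metadata)
  records <- data.frame(
    id = ids,
    species = vapply(meta, function(m) m[["species"]], character(1)),
    phylum = vapply(meta, function(m) m[["phylum"]], character(1)),
    residues = toupper(as.character(set)),
    source = vapply(meta, function(m) {
      if (is.na(m[["source"]])) source else m[["source"]]
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  validate_records(records)
}

parse_fasta_metadata <- function(header) {
  out <- c(species = "unknown", phylum = "unknown", source = NA_character_)
  rest <- sub("^\\S+\\s*", "", header)
  if (!nzchar(rest)) return(out)
  for (field in strsplit(rest, ";")[[1L]]) {
    kv <- strsplit(trimws(field), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L && kv[1L] %in% names(out)) {
      out[[kv[1L]]] <- trimws(kv[2L])
    }
  }
  out
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: headers carry
#' `id species=...; phylum=...; source=...` and sequences are wrapped.
#'
#' @param records a sequence-record table.
#' @param path output path.
#' @param width line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(sprintf(">%s species=%s; phylum=%s; source=%s",
                       records$id[i], records$species[i],
                       records$phylum[i], records$source[i]), con)
    seq <- records$residues[i]
    starts <- seq.int(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but rows may contain `-` gap characters and all
#' rows must have equal length. The result is the package's alignment
#' container: a named character vector of gapped rows.
#'
#' @param path path to an aligned FASTA file.
#' @return named character vector (one gapped row per sequence).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  as_alignment(rows)
}

#' Validate an alignment (named character vector of gapped rows)
#' @param rows named character vector; residues plus `-`, all equal length.
#' @return `rows`, checked.
#' @export
as_alignment <- function(rows) {
  if (length(rows) == 0L) stop("empty alignment")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named")
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length")
  }
  bad <- regexpr(sprintf("[^%s-]", paste(AA_ALPHABET_OK, collapse = "")), rows)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("alignment row '", names(rows)[i],
         "' has an invalid character at column ", bad[i])
  }
  rows
}

#' Read a BLAST-style tabular homology-hit file
#'
#' Expects the standard 12-column tab-separated layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, evalue, bitscore), no header row; lines starting
#' with `#` are skipped. Scientific-notation e-values are accepted.
#'
#' @param path path to the tab-separated file.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(rows)
  if (any(n_fields != 12L)) {
    bad <- which(keep)[which(n_fields != 12L)[1L]]
    stop("hit table line ", bad, " has ", n_fields[which(n_fields != 12L)[1L]],
         " columns (expected 12)")
  }
  if (length(rows) == 0L) return(empty_hit_table())
  m <- do.call(rbind, rows)
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = as.numeric(m[, 3L]),
    alignment_length = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gap_opens = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  validate_hits(hits)
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) {
    stop("hit table has a missing or negative e-value")
  }
  if (any(is.na(hits$percent_identity)) ||
      any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("hit table has a percent identity outside [0, 100]")
  }
  if (any(hits$alignment_length <= 0L)) {
    stop("hit table has a non-positive alignment length")
  }
  hits
}

#' Read a conserved-domain annotation table
#'
#' Six tab-separated columns: `seq_id`, `domain_name`, `start`, `end`,
#' `complete`, `evalue`. A header row is detected (and skipped) when the
#' third field of the first line is not numeric. Coordinates are 1-based
#' inclusive; when `records` is supplied, `end` is checked against the
#' annotated sequence's length.
#'
#' @param path path to the tab-separated file.
#' @param records optional sequence-record table for coordinate validation.
#' @return data.frame with the six columns above (`complete` is logical).
#' @export
read_domain_table <- function(path, records = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) return(validate_domains(empty_domain_table()))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(rows) > 0L && suppressWarnings(is.na(as.numeric(rows[[1L]][3L])))) {
    keep <- keep[-1L]
    rows <- rows[-1L]
  }
  n_fields <- lengths(rows)
  if (any(n_fields != 6L)) {
    i <- which(n_fields != 6L)[1L]
    stop("domain table line ", keep[i], " has ", n_fields[i],
         " columns (expected 6)")
  }
  if (length(rows) == 0L) return(validate_domains(empty_domain_table()))
  m <- do.call(rbind, rows)
  domains <- data.frame(
    seq_id = m[, 1L], domain_name = m[, 2L],
    start = as.integer(m[, 3L]), end = as.integer(m[, 4L]),
    complete = tolower(m[, 5L]) %in% c("true", "t", "1", "yes"),
    evalue = as.numeric(m[, 6L]),
    stringsAsFactors = FALSE
  )
  validate_domains(domains, records)
}

empty_domain_table <- function() {
  data.frame(seq_id = character(), domain_name = character(),
             start = integer(), end = integer(), complete = logical(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Validate a domain-annotation table
#' @param domains data.frame with columns `seq_id`, `domain_name`,
#'   `start`, `end`, `complete`, `evalue`.
#' @param records optional sequence-record table; when given, coordinates
#'   are checked against sequence lengths.
#' @return `domains`, checked.
#' @export
validate_domains <- function(domains, records = NULL) {
  bad_name <- setdiff(unique(domains$domain_name), DOMAIN_VOCABULARY)
  if (length(bad_name) > 0L) {
    stop("unknown domain name(s): ", paste(bad_name, collapse = ", "),
         "; expected one of: ", paste(DOMAIN_VOCABULARY, collapse = ", "))
  }
  bad <- which(domains$start < 1L | domains$start > domains$end)
  if (length(bad) > 0L) {
    stop("domain annotation for '", domains$seq_id[bad[1L]],
         "' has invalid coordinates ", domains$start[bad[1L]], "-",
         domains$end[bad[1L]])
  }
  if (!is.null(records)) {
    lens <- record_lengths(records)
    known <- domains$seq_id %in% names(lens)
    over <- which(known & domains$end > lens[domains$seq_id])
    if (length(over) > 0L) {
      i <- over[1L]
      stop("domain annotation for '", domains$seq_id[i], "' ends at ",
           domains$end[i], " but the sequence has only ",
           lens[[domains$seq_id[i]]], " residues")
    }
  }
  domains
}

#' Read a newick tree
#'
#' Wraps [ape::read.tree()] with a balance check that reports the character
#' offset of the first unbalanced parenthesis. Trees without branch lengths
#' are returned with all lengths 0 and attribute `lengths_missing = TRUE`
#' (with a warning).
#'
#' @param path path to a newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  text <- paste(readLines(path), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at character ", i, " of ", path)
  }
  if (depth > 0L) {
    stop("unbalanced '(': ", depth, " parenthesis/es never closed in ", path)
  }
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (is.null(tree$edge.length)) {
    warning("tree in ", path, " has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
    attr(tree, "lengths_missing") <- TRUE
  }
  if (any(tree$edge.length < 0)) stop("tree in ", path, " has a negative branch length")
  if (anyDuplicated(tree$tip.label)) {
    stop("tree in ", path, " has duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  tree
}

#' Write a tree to newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a data frame as a tab-separated file with a header row
#' @param rows a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column tip-to-taxon map
#'
#' Tab-separated with columns `id` and `phylum` (header optional).
#'
#' @param path path to the file.
#' @return named character vector mapping tip id to phylum.
#' @export
read_taxa <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxon map must have two columns (id, phylum)")
  if (identical(tolower(df[1L, 1L]), "id")) df <- df[-1L, , drop = FALSE]
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
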