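# independent oracles and fixture builders used across the suite

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA20_TEST) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# -- motif oracle: translate the bracket grammar to a PCRE lookahead and
#    collect every (overlapping) match start
brute_motif_starts <- function(seq, pattern, anchored = FALSE) {
  rx <- pattern
  rx <- gsub("x", sprintf("[%s]", paste(AA20_TEST, collapse = "")), rx,
             fixed = TRUE)
  rx <- gsub("\\[([A-Z])/([A-Z])/([A-Z])\\]", "[\\1\\2\\3]", rx)
  rx <- gsub("\\[([A-Z])/([A-Z])\\]", "[\\1\\2]", rx)
  if (anchored) {
    if (grepl(paste0("^", rx), seq, perl = TRUE)) 1L else integer(0)
  } else {
    m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
}

# -- alignment oracle: brute-force maximum over all global alignments
#    under affine gaps (gap of length L costs open + L * extend)
blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

brute_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, blosum62[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (j <= length(B)) {
      best <- max(best, -(gap_extend + if (last == "gb") 0 else gap_open) +
                    rec(i, j + 1L, "gb"))
    }
    if (i <= length(A)) {
      best <- max(best, -(gap_extend + if (last == "ga") 0 else gap_open) +
                    rec(i + 1L, j, "ga"))
    }
    best
  }
  rec(1L, 1L, "start")
}

# -- patristic oracle: shortest paths on the tree graph (igraph)
brute_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1L], to = tree$edge[, 2L]),
    directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  idx <- match(as.character(seq_len(n_tip)), rownames(d))
  out <- d[idx, idx]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# -- small fixture builders
make_records <- function(...) {
  seqs <- c(...)
  seq_records(names(seqs), unname(seqs), species = "testsp",
              phylum = "Arthropoda", source = "synthetic")
}

make_domains <- function(seq_id, domain_name, start, end, complete = TRUE,
                         evalue = 1e-80) {
  data.frame(seq_id = seq_id, domain_name = domain_name,
             start = as.integer(start), end = as.integer(end),
             complete = complete, evalue = evalue, stringsAsFactors = FALSE)
}

make_hits <- function(subject_id, evalue, percent_identity = 80,
                      query_id = "q1", alignment_length = 300L) {
  n <- length(subject_id)
  data.frame(query_id = rep_len(query_id, n), subject_id = subject_id,
             percent_identity = rep_len(percent_identity, n),
             alignment_length = rep_len(alignment_length, n),
             mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 300L,
             sstart = 1L, send = 300L, evalue = evalue,
             bitscore = 500, stringsAsFactors = FALSE)
}

write_hit_lines <- function(df, path) {
  cols <- lapply(df, as.character)
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  path
}
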