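#!/usr/bin/env Rscript
# Fetches the named PKA catalytic-subunit accessions used for the printed
# identity/similarity comparisons and writes them as a plain-text FASTA
# panel under inst/extdata/accessions/. Requires network access to NCBI
# E-utilities; run once from the repository root:
#
#   Rscript scripts/fetch_accessions.R
#
# The panel covers human PKA-Calpha (NP_002721.1) and PKA-Cbeta
# (P22694.2), Drosophila melanogaster PKA-C1 (NP_476977.1), Gecarcinus
# lateralis PKA-C_1 (PX409858), Carcinus maenas PKA-C_GLY2 (PX409857) and
# Penaeus vannamei PKA-C_GLY1 (XP_070000929.1). After fetching, the
# comparison in tests/testthat/test-acceptance.R runs automatically.

accessions <- c("NP_002721.1", "P22694.2", "NP_476977.1", "PX409858",
                "PX409857", "XP_070000929.1")

out_dir <- file.path("inst", "extdata", "accessions")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
out_fa <- file.path(out_dir, "pka_c_table2_panel.fasta")

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
url <- sprintf("%s?db=protein&id=%s&rettype=fasta&retmode=text", base,
               paste(accessions, collapse = ","))
raw <- tryCatch(readLines(url), error = function(e) {
  stop("could not reach NCBI E-utilities: ", conditionMessage(e),
       "\nThis script needs network access; rerun where NCBI is reachable.")
})

# normalize headers to the bare accession so tests can address records by id
raw <- vapply(raw, function(line) {
  if (startsWith(line, ">")) {
    acc <- sub("^>(\\S+).*$", "\\1", line)
    paste0(">", acc)
  } else {
    line
  }
}, character(1), USE.NAMES = FALSE)
writeLines(raw[nzchar(raw)], out_fa)

got <- sum(startsWith(raw, ">"))
if (got < length(accessions)) {
  warning("fetched only ", got, " of ", length(accessions), " accessions")
}
cat("wrote", got, "sequences to", out_fa, "\n")
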