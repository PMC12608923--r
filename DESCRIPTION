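Package: crustakin
Title: Curation, Motif Analysis and Classification of Crustacean PKA and
    PKC Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline bioinformatic characterization of decapod crustacean
    protein kinase A (PKA) and protein kinase C (PKC) homologs: e-value and
    identity filters for homology-hit tables, conserved-domain completeness
    screening, tree-based contamination flagging (long terminal branches and
    taxon-inconsistent placements), a degenerate N-terminal motif grammar and
    scanner, alignment consensus derivation, glycine-rich isoform detection,
    global pairwise alignment with grouped identity/similarity statistics,
    domain-architecture classification into PKA/PKC families with a decapod
    isoform nomenclature, and a seeded synthetic-data generator with planted
    ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
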