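# crustakin

Bioinformatic characterization of crustacean protein kinase A (PKA) and
protein kinase C (PKC) sequences, built for decapods and other non-model
invertebrates whose kinases cannot simply be mapped onto chordate isoform
names. The package is aimed at comparative physiologists and molecular
biologists curating PKA/PKC homologs from transcriptome or GenBank
searches: it filters homology hits, screens trees for contamination,
scans N-terminal regions for diagnostic motifs, computes grouped
identity/similarity statistics, and classifies each sequence into a
family, subtype and decapod isoform name — entirely offline, with a
seeded synthetic-data generator standing in for database downloads.

## What it computes

**Curation.** Reference hits are kept at e-value ≤ 1 × 10⁻⁷⁰ with percent
identity above 60% and ≥ 1 complete conserved domain; transcriptome
(CrusTome-style) hits at e-value ≤ 1 × 10⁻¹²⁰; PKA-R and PKC candidates
additionally need ≥ 2 complete conserved domains. Trees are screened for
contaminants two ways: a tip is a *long-branch* suspect when its terminal
branch exceeds both k·median (k = 5) and the Tukey fence Q3 + 1.5·IQR of
terminal lengths, and a *taxon-inconsistency* suspect when fewer than 2
of its m = 5 patristically nearest neighbors share its phylum (e.g. an
arthropod-labeled sequence inside a nematode clade).

**Motifs.** A degenerate-motif grammar (`x` = any residue, `[K/R]` =
alternation) covers the diagnostic N-terminal patterns: anchored
`MGNxxxx[K/R]` (chordate PKA-C) and `MGNxxxxK` (invertebrate PKA-C₁),
`FxxxW`, the decapod `MATL[M/T/A]A[F/T]`, the AKAP-related `IxI`/`VxV`,
the G2 myristoylation site, and the autoinhibitory sites `RRx[A/G]`
(PKA-RI pseudosubstrate) vs `RRxS` (PKA-RII substrate). Glycine-rich
N-terminal tracts (the crustacean GLY isoforms) are detected with a
25-residue window at ≥ 40% glycine.

**Identity/similarity.** Pairs are globally aligned (Needleman–Wunsch,
BLOSUM62, affine gaps: a gap of length L costs 10 + 0.5·L) and scored as

    identity   = 100 · #(identical columns) / #columns
    similarity = 100 · #(identical or same-group columns) / #columns

with the similarity groups GAVLI, FYW, CM, ST, KRH, DENQ, P.

**Classification.** Domain architecture resolves the families — PKA-R
(≥ 2 cAMP-binding), PKN (HR1 + kinase), aPKC (PB1 + C1 + kinase), cPKC
(C1 before C2 + kinase), novel PKC (C2 before C1 + kinase; delta-like vs
epsilon-like by nearest labeled exemplar), PKA-C (kinase only + N-terminal
motif evidence) — and the decapod nomenclature (PKA-C₁/C_GLY/C_D1,
PKA-RI/RII(_GLY), cPKC_D, nPKC_Dδ/ε, aPKC_D, PKN_D) is issued per species
in order of characterization.

## Worked example

```r
library(crustakin)

# a synthetic 2-species decapod kinase repertoire with planted truth
d  <- generate_dataset(sim_spec(n_species = 2, n_per_class = 1,
                                mu = 0.05, seed = 42))
cl <- classify_dataset(d$records, d$domains, panel = template_panel())
head(cl[, c("seq_id", "family", "subtype", "decapod_name")], 10)
#>                       seq_id            family subtype decapod_name
#>            species01_PKAC1_1             PKA-C     C_1      PKA-C_1
#>          species01_PKACGLY_1             PKA-C   C_GLY   PKA-C_GLY1
#>           species01_PKACD1_1             PKA-C    C_D1     PKA-C_D1
#>            species01_PKARI_1             PKA-R      RI     PKA-RI_1
#>        species01_PKARIIGLY_1             PKA-R RII_GLY  PKA-RII_GLY
#>             species01_cPKC_1              cPKC    <NA>      cPKC_D1
#>    species01_nPKCdeltalike_1   nPKC-delta-like    <NA>     nPKC_D1δ
#>  species01_nPKCepsilonlike_1 nPKC-epsilon-like    <NA>     nPKC_D1ε
#>             species01_aPKC_1              aPKC    <NA>      aPKC_D1
#>              species01_PKN_1               PKN    <NA>       PKN_D1
```

Every sequence lands in its planted family; the three PKA-C isoforms of
`species01` differ only N-terminally (their catalytic cores are
identical) and are told apart by the anchored MGN motif, the glycine
tract and the MATL motif respectively.

The grouped statistic on a 7-residue toy pair:

```r
aln <- global_align("MGNAAAK", "MGNAGIK")
round(ident_sim(aln), 1)
#>   identity similarity
#>       71.4      100.0
```

5 of 7 columns are identical (71.4%); the two mismatches, A↔G and A↔I,
both fall inside the GAVLI group, so all 7 columns are similar (100%).

A motif report for the first synthetic PKA-C₁:

```r
rep <- motif_report(d$records[1, ], d$domains)
rep[rep$present, c("check", "start", "end", "match")]
#>         check start end    match
#>  MGNxxxx[K/R]     1   8 MGNAAATK
#>      MGNxxxxK     1   8 MGNAAATK
#>         FxxxW    15  19    FAQLW
#>           VxV    21  23      VKV
#>            G2     2   2        G
```

A shell front end with `simulate`, `curate`, `treeqc`, `motifs`,
`identsim` and `run` subcommands ships under `inst/scripts/crustakin.R`.

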