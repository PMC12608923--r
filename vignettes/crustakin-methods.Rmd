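---
title: "Methods: curating and classifying crustacean PKA/PKC sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and classifying crustacean PKA/PKC sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crustakin)
```

## The problem

cAMP-dependent protein kinase (PKA) and protein kinase C (PKC) are
characterized almost entirely from chordate models, where catalytic and
regulatory subunits fall into well-resolved isoforms (PKA-Cα/β/γ,
PKA-RIα/β, RIIα/β, and twelve PKCs in five subfamilies). Invertebrate
sequences, including those of decapod crustaceans, do not segregate into
these chordate isoform clades; annotation pipelines that force chordate
names onto them mislead downstream physiology. Classifying a decapod
kinase therefore has to rest on features that *are* portable: domain
architecture, a small set of diagnostic N-terminal motifs, glycine-rich
N-terminal tracts, and similarity to labeled exemplars. crustakin
implements that workflow — from raw homology-hit curation to the decapod
isoform nomenclature — as composable, deterministic, offline-testable
functions.

## Curation model

Candidate sets are assembled from two kinds of searches and filtered by
thresholds that mirror standard practice for this protein family:

* **Reference hits** (curated protein databases): best e-value
  ≤ `1e-70` (inclusive), best percent identity strictly above 60, and at
  least one complete conserved domain. "Above 60%" is read literally as
  a strict inequality; a hit at exactly 60.0 is rejected. E-value bounds
  are inclusive because they are stated as "≤" thresholds.
* **Transcriptome hits** (multi-species crustacean assemblies): best
  e-value ≤ `1e-120`, with no identity or domain condition at this
  stage; deeper stringency compensates for the absence of curation in
  assembled transcriptomes.
* **Domain completeness**: PKA-R and PKC candidates additionally need at
  least two *complete* conserved domains; proteins sharing a single
  domain with the family (other cAMP-binding proteins, other kinases)
  are excluded this way.

Filters operate per subject on its best hit (minimum e-value, maximum
identity) because multiple query searches are concatenated; each filter
partitions its input exactly into kept and rejected-with-reason, is
idempotent on its own kept set, and is monotone in every threshold.
These three properties are enforced by tests.

### Tree-based contamination screening

Assembled transcriptomes of crustaceans frequently carry sequences from
parasites and commensals (nematodes, trematodes, mites). Two screens
flag suspects for manual review:

* **Long branches.** A tip is flagged only when its terminal branch
  exceeds *both* k·median(terminal lengths) with k = 5 *and* the Tukey
  upper fence Q3 + 1.5·IQR. No numeric criterion is standard for this
  step, so the dual rule was chosen to stay silent on trees whose
  branches are uniformly long (a k·median rule alone fires on any
  right-skewed length distribution; the fence alone fires on tight
  distributions with harmless spread). k is configurable; `k = Inf`
  disables the screen. Trees with fewer than 10 tips are refused because
  the null spread cannot be estimated.
* **Taxon inconsistency.** For each tip the m = 5 patristically nearest
  other tips are collected (distance ties broken by tip id so results
  are deterministic); a tip with fewer than 2 same-phylum neighbors is
  flagged. The neighborhood formulation deliberately avoids clade
  language: the trees being screened are unrooted at this stage, so
  "inside a foreign clade" is not well defined, while "surrounded by
  foreign tips at small patristic distance" is. With m = 1 a tip can
  never reach 2 matching neighbors and is always flagged — a documented
  degenerate setting; m ≥ 3 is recommended.

The published workflow re-validated flagged sequences by re-searching
them against the full protein database; that round trip needs network
access and taxonomy services and is out of scope here — the screens
produce the review list, not the verdict.

## Motif grammar and scanning

Patterns are written exactly as printed in the comparative literature:
uppercase literals, `x` for any canonical residue, and bracketed
alternations (`MGNxxxx[K/R]`, `MATL[M/T/A]A[F/T]`). Compilation produces
one residue set per position; scanning reports every match, including
overlaps, left to right. Two deliberate semantics:

* anchored motifs (the MGN starts) match only at residue 1;
* the unknown residue `X` matches nothing — not literals, not the
  wildcard — so ambiguous sequence can never *create* motif evidence.

The autoinhibitory-site scan that distinguishes regulatory subunit types
(RRx[A/G] → RI pseudosubstrate, RRxS → RII phosphorylatable substrate)
is restricted to the linker between the dimerization/docking domain and
the first cAMP-binding domain whenever annotations are available,
because cAMP-binding domains contain arginine-rich stretches that
produce spurious RRxS hits. Without annotations the whole sequence is
scanned and a warning raised. Both motifs firing (at different
positions) yields `ambiguous` rather than a silent preference.

### Consensus and conservation profiles

Alignment consensus is frequency-based, per column over non-gap
entries: a residue at frequency ≥ 0.7 is emitted; else the top two
residues are emitted as `[A/B]` when they jointly reach 0.7 and each
reaches 0.2; else `x`; columns more than half gaps print `-`. The 0.7
thresholds are package choices (the published consensus strings come
from a plotting script whose thresholds are not stated); they are
exposed as arguments, and the defaults reproduce clean planted
alternations such as a 50/50 K/R column → `[K/R]`. Frequency ties break
alphabetically so output is deterministic. Conservation profiles against
a designated reference row (the chordate exemplar, matching how such
figures are drawn) use strict bins >80 / >60 / >40 / ≤40 percent, with
reference-gap columns marked undefined.

### Glycine-rich tracts

The crustacean-specific GLY isoforms carry elongated glycine-rich
N-terminal tracts. "Glycine-rich" is quantified as: some 25-residue
window within the N-terminal region (sequence start to just before the
first kinase/cAMP-binding domain) with glycine fraction ≥ 0.4;
overlapping qualifying windows are merged into maximal regions. The
window and fraction are package calibrations — chosen so that tracts of
the planted GLY templates (~30–40 residues at ~80% glycine) pass with a
wide margin even after 5–10% substitution noise, while ordinary
N-termini at background glycine frequencies (~7%) never do — and both
are exposed as arguments.

## Grouped identity and similarity

Pairs are aligned globally (Needleman–Wunsch with affine gaps, BLOSUM62,
gap open 10, gap extend 0.5, terminal gaps penalized; the dynamic
program is delegated to Biostrings and verified against exhaustive
alignment enumeration in the tests). The statistic is computed on the
resulting columns: identity counts equal residues; similarity
additionally counts residues in the same group of the GAVLI / FYW / CM /
ST / KRH / DENQ / P scheme. Gap-versus-residue columns are counted in
the denominator and are never identical or similar; `X` counts as
mismatch even against itself. Two denominator conventions are supported
— the full alignment length (default) and the shorter degapped sequence
— because the web tool used for the published tables does not state its
convention; the acceptance comparison calibrates the choice on a
chordate-versus-chordate pair before judging the rest. The published
values were produced by a different (structure-informed, iterative)
aligner, so agreement is expected within a tolerance (±2 percentage
points), not bit-exactly. Values are kept at full precision internally
and rounded to one decimal only when written.

## Architecture classifier and nomenclature

Families are resolved by a fixed-order rule walk over the domain
annotations: PKA-R (≥ 2 cAMP-binding; D/D optional, truncated subunits
exist), then PKN (≥ 1 HR1 + kinase), aPKC (PB1 + single C1 + kinase),
cPKC (C1 before C2 + kinase), novel PKC (C2 before C1 + kinase), and
PKA-C (kinase only, plus N-terminal motif evidence). The novel-PKC
order constraint "C2 precedes C1" is an assumption read off subfamily
domain schematics and is overridable (`novel_order`). Overlapping
annotations of different names sharing more than half the shorter span
are rejected as contradictory input rather than silently resolved.

Decisions that architecture cannot make are delegated to a labeled
exemplar panel via maximal grouped similarity (ties: identity, then
lexicographic exemplar id, recorded as ties): novel delta-like vs
epsilon-like, and the finer regulatory subtypes (RI_1 vs RI_D1, RII_GLY
vs RII_D1) for which no printed motif rule exists. Such calls carry
`confidence = "nearest_reference_only"`. When no panel is supplied a
novel PKC keeps the placeholder family `"nPKC"` — the two subfamilies
are architecturally identical, so pretending to know more would be
wrong. PKA-C subtypes use the priority glycine tract > MATL motif >
anchored MGN, most-specific-first (a glycine tract is the rarest
signal); the order is configurable. The classifier never assigns
chordate isozyme names (α/β/γ/δ/…) to non-chordate inputs.

Decapod names are issued from a per-species registry in order of
characterization: `cPKC_D1`, `nPKC_D1δ`, `PKN_D3`, `PKA-C_GLY2`, and so
on. The ordinal is a naming convention, not a biological claim about
orthology between equally-numbered isoforms of different species.

## What the synthetic data emulates — and what it does not

`generate_dataset()` plants the structure the analysis assumes: ten
classes covering the decapod repertoire, class-specific N-terminal
templates carrying the diagnostic motifs at known positions, domain
layouts in the proportions of the real families (PKA-C ≈ 300–340 aa
with a C-terminal kinase domain, PKN ≈ 900 aa with three N-terminal HR1
repeats, …), glycine tracts for the GLY classes, and — mirroring the
striking observation in real decapods — a catalytic core mutated once
per species and shared identically by all isoform classes of the same
family, so isoforms differ only N-terminally. Substitutions are
background-frequency-weighted and never touch planted motif literals;
single-residue indels (rate 0.005) avoid planted motifs and a ±3 buffer
around domain boundaries, and domain coordinates are shifted
consistently. Everything is deterministic given the seed. Template
filler in regulatory-subunit linkers is screened free of RR dipeptides
outside the planted autoinhibitory site so that planted RI/RII truth
labels are unambiguous by construction.

`generate_contaminated_tree()` produces coalescent-topology trees whose
terminal branches are clock-like (lognormal, sdlog 0.35) rather than raw
coalescent pendant lengths: a curated single-protein tree has
homogeneous terminal branches, and that homogeneity is the null the
long-branch screen assumes. Raw coalescent pendant edges are
exponential-tailed and repeatedly cross the Tukey fence on perfectly
clean trees, which would make "planted contaminant" ill-defined.
Contamination is planted as 10–100× terminal inflation and cross-clade
relabeling.

What passing tests on these data do **not** show: robustness to
alignment error (domain annotations are generated noise-free, whereas
real conserved-domain searches have fuzzy boundaries and missed
domains), to fragmented transcripts (all synthetic sequences are
full-length; real assemblies truncate N-termini, exactly where the
diagnostic motifs live), to compositional bias, or to genuinely novel
architectures outside the ten planted classes. The recovery accuracies
reported by the acceptance script are therefore upper bounds specific to
the planted-structure regime.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive everywhere.
* All tie-breaks (consensus residues, motif ordering, nearest-reference
  exemplars, patristic neighbor order) are deterministic, so identical
  inputs give byte-identical outputs; the pipeline sorts all artifacts
  by sequence id.
* Degenerate inputs are explicit: empty N-terminal regions are flagged,
  search spans shorter than the glycine window return empty with a
  warning, trees under 10 tips refuse the long-branch screen, sequences
  of only `X` are unalignable, malformed tables are rejected with line
  numbers rather than truncated.
* Problem sizes in tests and the acceptance script — 20 sequences per
  class, three seeded replicates, 40-tip trees, exhaustive alignment
  enumeration up to length 6 over a 4-letter alphabet — were chosen as
  the smallest sizes at which the measured quantities are stable across
  seeds while the whole suite stays fast enough to run routinely.

## Known limitations

* Pairwise Needleman–Wunsch stands in for the structure-informed
  iterative aligner used for the published tables; printed values are
  reproduced within tolerance, not exactly, and `AlignParams` is exposed
  for calibration.
* The conserved-domain annotations are consumed, not computed; a real
  run needs an external domain search, exported to the 6-column table.
* The re-validation of flagged contaminants against a remote database is
  reduced to the flagging step plus a report for manual follow-up.
* Reference positions quoted in the comparative literature are
  alignment-column coordinates of specific published MSAs; this package
  reports sequence coordinates and leaves any column mapping to the
  caller.
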