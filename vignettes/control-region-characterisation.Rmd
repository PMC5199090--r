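---
title: "Characterising complete mitochondrial control-region alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising complete mitochondrial control-region alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlregion)
```

## The problem

The mitochondrial control region (d-loop) is the fastest-evolving part of
the mitochondrial genome and the workhorse marker of population genetics and
wildlife forensics. In practice most studies sequence only a short
"hypervariable region I" (HVRI) from its left domain — yet the length and
position of that region are defined inconsistently across studies and taxa,
and polymorphisms outside it are routinely discarded. For orang-utans, the
predominantly analysed segments cover roughly a quarter to two-fifths of the
region, and shorter segments merge haplotypes that complete sequences can
tell apart.

`ctrlregion` implements the complete characterisation workflow on an
alignment of full control-region sequences:

1. **Diversity indices** (`diversity_summary()`): number of haplotypes
   $h$, segregating sites $S$, total mutations $\eta$ (the minimum-mutation
   count, $\sum_{\text{sites}} (\text{states} - 1)$), mean pairwise
   differences $k$, and per-site diversity $\pi = k / \text{sites}$.
2. **Hypervariable-region delimitation** (`window_profile()`,
   `delimit_regions()`): sliding-window $\pi$ profiles and a conservation
   threshold derived from $S$.
3. **Segment algebra** (`trim_alignment()`, `excise_and_concatenate()`):
   cutting the alignment to published marker segments, or excising a segment
   and concatenating the "oft-ignored bases".
4. **Haplotype resolution and species diagnosis** (`resolution_report()`,
   `classify_species_by_deletion()`, `in_silico_pcr()`).
5. **Clade concordance** (`distance_matrix()`, `nj_tree()`,
   `concordance()`): do trees built from a short segment and from the
   remainder place sequences into the same subpopulation clades?
6. **A synthetic generator** (`syn_config()`, `generate_alignment()`) that
   plants all of the above structure with known ground truth.

## Gap policies

Indels make every scalar statistic ambiguous, so the gap policy is an
explicit argument everywhere:

* `complete_deletion` (default): every column containing `-` or `N` is
  removed before anything is computed. This is the convention consistent
  with published tables whose "number of sites" is smaller than the
  alignment length, and it makes $S$, $\eta$ and per-pair differences
  exactly additive over any column partition.
* `pairwise_deletion`: gaps and `N` are missing data, dropped per column
  for site statistics and per pair for differences.
* `include_gaps`: `-` is a fifth character state, so an indel difference
  counts; `N` remains missing.

The primary literature is itself contradictory about whether gap sites were
included in the sliding-window profiles, so both conventions are exposed
rather than resolved. `N` never separates haplotypes: a record joins the
first compatible haplotype in first-occurrence order, which keeps numbering
deterministic; gaps separate haplotypes by default (`gap_as_state = TRUE`)
because real species-diagnostic indels are exactly what full-length
haplotyping should see.

## Delimiting hypervariable regions

Windows of 100 columns advancing by 25 (the published profile convention)
are anchored at column 1 with no partial trailing window. A window is
*hypervariable* when its observed segregating-site count exceeds a
multiplier (default 1.0) times its expected count under uniform scatter,
$S \cdot w / n_\text{sites}$, scaled by the window's own analysed-site
count when gaps are present.

Converting window classes into region boundaries is where conventions
matter. Snapping a merged region to the outermost columns of its
contributing windows biases every boundary outward by up to half a window:
with the default multiplier, any window with about a third of its columns
inside a hotspot classifies hypervariable, so a block ending at column 380
would be reported as ending near 425. We therefore label each *column* by a
strict majority vote of the windows covering it (ties conserved) and merge
equal-label runs. This keeps boundaries within one step (±25 columns) of a
planted block boundary, which we verify by parameter recovery over 100
seeded replicates (`hvr_recovery_experiment()`), and it degrades gracefully
to the window-extent answer when signal is unambiguous. Columns not covered
by any window (the trailing `n_cols mod step` columns) are unlabelled.

The leftmost hypervariable interval is flagged `HVRI`. Boundaries are
reported both in alignment columns and, through `build_coordinate_map()`
and `regions_to_reference()`, in reference coordinates (e.g. positions
15484 onward on a complete mitochondrial genome), because the two framings
differ wherever the reference row carries gaps. No formal change-point
detection is attempted, and no HVRII/HVRIII labels are assigned.

## Trees and concordance

Bayesian tree estimation is deliberately out of scope: the concordance
questions asked here are topological and answerable with any consistent
estimator on clean signal. The package builds neighbor-joining trees from
p- or K2P distances and exports sequential NEXUS (`export_nexus()`) so the
identical alignments can be run through external Bayesian software.
Determinism contracts: taxa are sorted lexicographically before
agglomeration, and negative NJ branches are clamped to zero with the
deficit moved to the sibling branch.

K2P is undefined ("saturated") when $1 - 2P - Q \le 0$; saturated pairs are
assigned the maximum finite distance observed and flagged. Because an 8×
mutational hotspot drives exactly this regime between deeply diverged
clades, the concordance experiment defaults to p-distances, which remain
well-defined; K2P is available and cross-checked against an independent
implementation in the tests.

Concordance is operationalised in two parts, since "concordantly resolved"
is qualitative in the source literature. *Monophyly* is tested per labelled
group on the tree pruned to labelled and outgroup leaves — unlabelled query
sequences nested inside a group's clade should not break it. *Assignment*
ascends from each query tip to the smallest enclosing clade that contains
any labelled leaves: a single label there assigns the query, mixed labels
report `"unassigned"` (never a silent attribution). Agreement between two
trees is the fraction of queries assigned identically.

## The synthetic generator

`generate_alignment()` evolves sequences down a star-of-stars genealogy —
root → outgroup ancestor and clade ancestors → haplotypes — rather than a
full coalescent: it is sufficient to plant clades and hotspots and trivial
to reason about. Defaults emulate the study conditions: a 1020-column
alignment of 38 sequences (4 clades × 9 haplotypes + 2 deep outgroups), one
dominant left-domain block (columns 1–380 at 8× rate), per-site
substitution probabilities 0.01 (clade branches), 0.005 (tip branches) and
0.08 (outgroup branch), a 4:1 transition bias so p- and K2P distances
differ measurably, and a single 15-column diagnostic deletion at columns
986–1000 carried by the first two clades — mirroring the species-diagnostic
deletion that separates ~1000 bp from ~1011–1016 bp control regions.
Substitution probabilities are capped at 0.75; indels occur only at
configured positions so truth intervals stay exact; a fixed config and seed
give byte-identical FASTA.

What the generator does *not* emulate: recombination-free but
non-star genealogies, heteroplasmy, numts, sequencing error, and random
indel processes. Passing parameter-recovery tests therefore demonstrates
correctness of the estimators under planted structure, not robustness to
every property of field data.

## Numerical and degenerate-input choices

* Coordinates are 1-based with inclusive ranges everywhere.
* An alignment whose analysed-column set is empty under `complete_deletion`
  returns $h = 1$, $S = \eta = k = \pi = 0$.
* Windows with no analysed column carry $\pi = 0$ and an `empty` flag.
* `k` is reported to 3 decimals in tables, full precision internally.
* The deletion classifier prefers locus detection (flanking 12-mers, ≤2
  mismatches per flank, locus "present" when the flanks enclose at least
  half the expected locus length) and falls back to the degapped length,
  split at 1005/1006 bp — the midpoint of the published species ranges. A
  deletion-sized sequence whose locus is detectably present is reported
  `indeterminate` with a warning.
* In-silico PCR uses a Hamming-only mismatch model with the three
  3'-terminal bases exact at any setting, and rejects products outside
  200–5000 bp as wrong-template/numt-suspect.

## Problem sizes

The shipped validation works at desk scale, chosen to exercise every code
path rather than to benchmark: 200 random toy alignments (≤8 × ≤60) against
a brute-force oracle under all three gap policies; 100 seeded generator
replicates for boundary recovery; 50 random 8-taxon additive matrices for
NJ recovery; 5-clade panels of 37 sequences for concordance. Reproducing
the published orang-utan table additionally requires the one-time GenBank
fetch in `scripts/fetch_genbank.R` (network and MAFFT), after which
`characterise_panels()` produces the segment-by-segment tables and the
full-table test in `tests/testthat/test-acceptance.R` runs against the
curated alignment.
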