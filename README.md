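# ctrlregion

Characterisation of complete mitochondrial DNA control-region alignments,
for population geneticists and wildlife forensic scientists who are asked —
or tempted — to sequence only a short "hypervariable region I" of the
d-loop. The package quantifies exactly what a shorter marker segment sees
and what it misses, on real alignments or on synthetic ones with known
ground truth.

## What it computes

Given an alignment of complete control-region sequences, `ctrlregion`
computes the classical diversity indices under explicit gap policies
(complete deletion, pairwise deletion, or gaps as a fifth state):

- number of haplotypes *h* (missing data never separates haplotypes),
- segregating sites *S* and total mutations *η* = Σ(states − 1) per site,
- mean pairwise differences *k* and per-site diversity *π = k / sites*;

delimits conserved versus hypervariable regions from sliding-window
profiles (window 100, step 25 by default), classifying windows against the
uniform-scatter expectation *S·w / n* of segregating sites per window;
trims the alignment to published marker segments (a built-in registry
carries the orang-utan left-domain segments of six prior studies in both
alignment and reference coordinates) or excises a segment and concatenates
the remaining "oft-ignored bases"; measures each segment's haplotype
resolution; classifies species by a diagnostic 15 bp deletion; runs
in-silico PCR with the built-in control-region primers; and tests whether
neighbor-joining trees built from a segment and from its remainder place
sequences into concordant subpopulation clades (Robinson–Foulds distance,
per-group monophyly, and query-assignment agreement), with sequential NEXUS
export for external Bayesian software.

A synthetic generator (`generate_alignment()`) plants hypervariable blocks,
clade structure, a transition bias and diagnostic indels with known truth,
so the whole pipeline is testable without downloading anything.

## Worked example

```r
library(ctrlregion)

gen <- generate_alignment(syn_config(), seed = 7)   # 38 sequences, 1020 columns
aln <- gen$alignment

diversity_summary(aln)
#> <cr_diversity> n = 38, sites = 1005 (complete_deletion)
#>   h = 38, S = 544, eta = 785, k = 104.303, pi = 0.10378

reg <- delimit_regions(window_profile(aln), aln)
as.data.frame(reg)
#>   start  end         label  hvri
#> 1     1  375 hypervariable  TRUE
#> 2   376 1000     conserved FALSE

resolution_report(aln, segment_spec("left_domain", cbind(33L, 355L)))
#> <cr_resolution> segment left_domain: 38 / 38 haplotypes discerned (100%)
```

The summary reads: all 38 synthetic sequences are distinct haplotypes; of
the 1005 gap-free columns, 544 are polymorphic, carrying 785 inferred
mutations, and two sequences differ at 104.3 sites on average. The
delimitation recovers the planted left-domain hotspot (columns 1–380 at 8×
rate) as a single hypervariable interval within one window step, and the
trailing 20 columns past the last full window are unlabelled. On this
default panel the left-domain segment still discerns every haplotype —
sequences here are far more diverged than real matrilines; configs with
between-clade signal confined outside the segment (see
`tests/testthat/test-discrimination.R`) show the segment merging haplotypes
that the full region separates.

Segment-by-segment tables in the published layout come from
`diversity_table()`:

```r
specs <- list(segment_spec("left_domain", cbind(33L, 355L)),
              segment_spec("complete", cbind(1L, 1020L)))
diversity_table(aln, specs)
#>       segment n_sites extent_percent positions  h   S eta       k
#> 1 left_domain     323             32   033-355 38 312 507  72.743
#> 2    complete    1005            100  001-1020 38 544 785 104.303
```

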