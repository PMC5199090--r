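Package: ctrlregion
Title: Characterisation of Complete Mitochondrial Control-Region Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterising complete mitochondrial DNA
    control-region alignments in population-genetic and forensic studies.
    Computes the classical diversity indices (number of haplotypes,
    segregating sites, total mutations, mean pairwise differences) under
    explicit gap-handling policies, profiles nucleotide diversity in
    sliding windows to delimit hypervariable versus conserved regions,
    trims alignments to the coordinate ranges of previously published
    marker segments or excises a segment and concatenates the remainder,
    quantifies the haplotype resolution of each segment, classifies
    species by a diagnostic deletion, performs in-silico PCR, and tests
    whether trees built from different portions of the control region
    place sequences into concordant clades.  A synthetic alignment
    generator with known hypervariable blocks, clade structure and
    diagnostic indels makes the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
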