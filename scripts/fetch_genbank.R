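#!/usr/bin/env Rscript
# One-time fetch of the published orang-utan control-region sequences from
# GenBank, de-duplication at full control-region resolution, alignment with
# MAFFT, and installation of the curated alignment under inst/extdata/ so
# that characterise_panels() and the full-table acceptance test can run.
#
# Requires network access to NCBI E-utilities and the `mafft` executable on
# PATH.  Run from the repository root:
#     Rscript scripts/fetch_genbank.R

suppressPackageStartupMessages(library(ctrlregion))

novel <- c(sprintf("KX4275%02d", 42:74), sprintf("KU5239%02d", 75:77))
published <- c("X97707", "X97708", "X97709", "X98472")
# D38115 carries an 81 bp deletion and disputed provenance; excluded.
accessions <- c(novel, published)

fetch_fasta <- function(accs, out) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
  url <- sprintf("%s?db=nuccore&id=%s&rettype=fasta&retmode=text",
                 base, paste(accs, collapse = ","))
  download.file(url, out, quiet = TRUE)
  out
}

raw_fa <- tempfile(fileext = ".fasta")
fetch_fasta(accessions, raw_fa)
seqs <- read_fasta(raw_fa)
names(seqs) <- sub("\\..*$", "", sub(" .*$", "", names(seqs)))

# The complete-genome records contribute only their control region
# (positions 15484-16499 on X97707); extract it by in-silico PCR with the
# flanking primers and trim the coding anchors off afterwards via the
# published coordinates.
genome_ids <- names(seqs)[nchar(seqs) > 10000]
for (id in genome_ids) {
  s <- seqs[[id]]
  seqs[[id]] <- substr(s, 15484L, min(16499L, nchar(s)))
}

# de-duplicate at full control-region resolution (one novel haplotype is
# identical to a published full-genome record)
keep <- !duplicated(degap(toupper(seqs)))
message(sprintf("dropping %d duplicate sequence(s)", sum(!keep)))
seqs <- seqs[keep]

unaln <- tempfile(fileext = ".fasta")
write_fasta(seqs, unaln)
aln_fa <- file.path("inst", "extdata", "orangutan_cr_alignment.fasta")
dir.create(dirname(aln_fa), recursive = TRUE, showWarnings = FALSE)
status <- system2("mafft", c("--auto", unaln), stdout = aln_fa)
if (status != 0L) stop("mafft failed")

aln <- cr_alignment(read_fasta(aln_fa))
message(sprintf("curated alignment: %d records x %d columns", nrow(aln), ncol(aln)))
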