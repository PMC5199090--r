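# End-to-end reproduction of the segment-by-segment diversity tables from a
# curated alignment of complete orang-utan control-region sequences.  The
# alignment itself must be fetched from GenBank and aligned once (see
# scripts/fetch_genbank.R); this package ships no sequence data.

#' Path of the curated control-region alignment, if present
#'
#' `scripts/fetch_genbank.R` downloads the study accessions from GenBank,
#' de-duplicates them at full control-region resolution, aligns them and
#' writes the result here.  Returns `NA` when the file has not been
#' generated (e.g. on systems without network access).
#'
#' @return Path to `orangutan_cr_alignment.fasta`, or `NA_character_`.
#' @export
curated_alignment_path <- function() {
  p <- system.file("extdata", "orangutan_cr_alignment.fasta", package = "ctrlregion")
  if (nzchar(p) && file.exists(p)) p else NA_character_
}

#' Segment-by-segment diversity tables for a curated alignment
#'
#' Runs the full characterisation over a complete control-region alignment:
#' for the whole panel and for each species separately (when labels are
#' supplied), computes the diversity summary of the complete alignment, of
#' each registry segment, and of the "oft-ignored" remainder after excising
#' the species' predominantly analysed segment (the 323-column left-domain
#' segment for Bornean panels, the 386-column segment for Sumatran panels).
#'
#' @param aln A complete control-region [cr_alignment].
#' @param species Optional named character vector id -> species label
#'   (`"sumatran"` / `"bornean"`); ids absent from it are used only in the
#'   all-sequence panel.
#' @param policy A [gap_policy()] (default `complete_deletion`, the
#'   convention consistent with tabulated analysed-site counts smaller than
#'   the alignment length).
#' @return Named list of data frames (one per panel) as returned by
#'   [diversity_table()], each with an extra complete-CR and, for species
#'   panels, an oft-ignored-bases row.
#' @export
characterise_panels <- function(aln, species = NULL, policy = "complete_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  reg <- segment_registry()$alignment
  full_spec <- function(a) segment_spec("complete_CR", cbind(1L, ncol(a)))
  one_panel <- function(a, remainder_of = NULL) {
    specs <- reg[vapply(reg, function(sp) max(sp$ranges[, "end"]) <= ncol(a), logical(1))]
    specs <- c(specs, list(complete_CR = full_spec(a)))
    if (!is.null(remainder_of)) {
      specs <- c(specs, list(oft_ignored = segment_complement(reg[[remainder_of]], ncol(a))))
    }
    diversity_table(a, specs, policy)
  }
  out <- list(all = one_panel(aln))
  if (!is.null(species)) {
    for (sp in unique(stats::na.omit(species))) {
      ids <- intersect(rownames(aln), names(species)[species == sp])
      if (length(ids) < 2L) next
      sub <- subset_records(aln, ids)
      remainder_of <- if (identical(sp, "bornean")) "jalil_arora" else "nater2013"
      out[[sp]] <- one_panel(sub, remainder_of = remainder_of)
    }
  }
  out
}
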