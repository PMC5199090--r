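# High-level experiments used for validation and calibration-free parameter
# recovery: hypervariable-block boundary recovery, NJ topology recovery,
# clade concordance on synthetic panels, and species classification by the
# diagnostic deletion.

#' Hypervariable-block boundary recovery on synthetic replicates
#'
#' Generates `n_rep` alignments from `config`, runs the sliding-window scan
#' and region delimitation on each, and scores a replicate as recovered when
#' the leftmost hypervariable interval's boundaries both fall within
#' `tol` columns of the planted dominant block.
#'
#' @param n_rep Number of replicates (default 100).
#' @param seed Base seed; replicate `r` uses `seed * 1000 + r`.
#' @param tol Boundary tolerance in columns (default 25, one step).
#' @param config A [syn_config()]; the planted block is `config$blocks[[1]]`.
#' @param window_length,step,threshold_multiplier Scan parameters.
#' @return List with `rate` (fraction recovered), `n_rep` and a `details`
#'   data frame (`seed`, `start`, `end`, `recovered`).
#' @export
hvr_recovery_experiment <- function(n_rep = 100L, seed = 1L, tol = 25L,
                                    config = syn_config(),
                                    window_length = 100L, step = 25L,
                                    threshold_multiplier = 1) {
  b <- config$blocks[[1L]]
  rows <- lapply(seq_len(n_rep), function(r) {
    rep_seed <- as.integer(seed) * 1000L + r
    gen <- generate_alignment(config, seed = rep_seed)
    prof <- window_profile(gen$alignment, window_length, step)
    reg <- delimit_regions(prof, gen$alignment, threshold_multiplier)
    hv <- reg[reg$hvri, , drop = FALSE]
    if (nrow(hv) == 0L) {
      return(data.frame(seed = rep_seed, start = NA_integer_, end = NA_integer_,
                        recovered = FALSE))
    }
    data.frame(seed = rep_seed, start = hv$start, end = hv$end,
               recovered = abs(hv$start - b[1L]) <= tol & abs(hv$end - b[2L]) <= tol)
  })
  details <- do.call(rbind, rows)
  list(rate = mean(details$recovered), n_rep = n_rep, details = details)
}

#' Neighbor-joining topology recovery from additive distances
#'
#' Draws random unrooted trees, computes their exact tree (additive)
#' distances and checks that neighbor joining reconstructs each generating
#' topology (Robinson-Foulds distance zero).
#'
#' @param n_rep Number of random trees (default 50).
#' @param n_taxa Taxa per tree (default 8).
#' @param seed RNG seed.
#' @return List with `n_recovered`, `n_rep` and `rate`.
#' @export
nj_recovery_experiment <- function(n_rep = 50L, n_taxa = 8L, seed = 1L) {
  set.seed(as.integer(seed))
  ok <- vapply(seq_len(n_rep), function(r) {
    tree <- ape::rtree(n_taxa, rooted = FALSE,
                       br = function(n) stats::runif(n, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(tree)
    est <- nj_tree(dm)
    rf_distance(est, tree) == 0L
  }, logical(1))
  list(n_recovered = sum(ok), n_rep = n_rep, rate = mean(ok))
}

#' Clade concordance between a marker segment and the remainder
#'
#' Generates a clade-structured panel, labels part of each clade, builds
#' neighbor-joining trees from the full alignment, from the alignment
#' trimmed to `segment`, and from the remainder after excising it, and
#' measures (i) the fraction of unlabelled query sequences each tree
#' assigns to its generating clade and (ii) the segment-versus-remainder
#' assignment agreement.
#'
#' @param seed RNG seed for the generator.
#' @param clade_divergence Between-clade divergence knob passed to
#'   [syn_config()].
#' @param n_clades Number of clades (default 5).
#' @param haps_per_clade Haplotypes per clade (default 7).
#' @param n_labelled Labelled sequences per clade; the rest are queries
#'   (default 4).
#' @param segment A [segment_spec()]; default the 323-column left-domain
#'   segment, columns 33-355.
#' @param config Optional full [syn_config()] override; `clades` and
#'   `clade_divergence` are rebuilt from the arguments above when absent.
#' @param model Distance model for tree building; the default `"p"` stays
#'   well-defined at hotspot-level divergence, where K2P can saturate.
#' @return List with `accuracy` (named: full, segment, remainder),
#'   `agreement_segment_remainder`, and the [concordance()] `report`.
#' @export
concordance_experiment <- function(seed = 1L, clade_divergence = 0.01,
                                   n_clades = 5L, haps_per_clade = 7L,
                                   n_labelled = 4L,
                                   segment = segment_spec("left_domain", cbind(33L, 355L)),
                                   config = NULL, model = "p") {
  if (is.null(config)) {
    clades <- stats::setNames(rep(as.integer(haps_per_clade), n_clades),
                              sprintf("CL%d", seq_len(n_clades)))
    config <- syn_config(clades = clades, clade_divergence = clade_divergence)
  }
  gen <- generate_alignment(config, seed = seed)
  aln <- gen$alignment
  truth <- gen$truth$labels
  og <- truth$id[truth$is_outgroup]
  labelled <- unlist(lapply(split(truth$id[!truth$is_outgroup],
                                  truth$clade[!truth$is_outgroup]),
                            utils::head, n_labelled))
  groups <- ifelse(truth$id %in% labelled, truth$clade, NA_character_)
  labels <- group_labels(truth$id, groups, outgroup = og)
  build <- function(a) nj_tree(distance_matrix(a, model = model))
  trees <- list(full = build(aln),
                segment = build(trim_alignment(aln, segment)),
                remainder = build(excise_and_concatenate(aln, segment)))
  report <- concordance(trees, labels)
  truth_of <- stats::setNames(truth$clade, truth$id)
  accuracy <- apply(report$assignments, 2L, function(a) {
    if (length(a) == 0L) return(NA_real_)
    mean(a == truth_of[rownames(report$assignments)])
  })
  list(accuracy = accuracy,
       agreement_segment_remainder = report$agreement["segment", "remainder"],
       report = report)
}

#' Species classification accuracy on synthetic panels
#'
#' Generates panels under the default diagnostic-deletion configuration and
#' classifies every ingroup sequence with [classify_species_by_deletion()],
#' deriving the deletion locus from one carrier and one non-carrier
#' reference per panel.
#'
#' @param n_panels Number of panels (default 6; with the default config
#'   each panel contributes 36 classified sequences).
#' @param seed Base seed.
#' @param config A [syn_config()] whose first indel is the diagnostic
#'   deletion.
#' @return List with `n_classified`, `n_correct` and `accuracy`.
#' @export
species_classification_experiment <- function(n_panels = 6L, seed = 1L,
                                              config = syn_config()) {
  n_ok <- 0L
  n_tot <- 0L
  for (p in seq_len(n_panels)) {
    gen <- generate_alignment(config, seed = as.integer(seed) * 1000L + p)
    seqs <- alignment_sequences(gen$alignment)
    truth <- gen$truth$labels
    carriers <- gen$truth$indel_carriers[[1L]]
    ingroup <- truth$id[!truth$is_outgroup]
    ref_without <- seqs[[carriers[1L]]]
    ref_with <- seqs[[setdiff(ingroup, carriers)[1L]]]
    locus <- find_deletion_locus(ref_with, ref_without)
    for (id in ingroup) {
      lab <- classify_species_by_deletion(seqs[[id]], locus = locus)
      want <- if (id %in% carriers) "bornean-like" else "sumatran-like"
      n_ok <- n_ok + as.integer(lab == want)
      n_tot <- n_tot + 1L
    }
  }
  list(n_classified = n_tot, n_correct = n_ok, accuracy = n_ok / n_tot)
}

#' Fraction of a mitochondrial genome occupied by the control region
#'
#' @param cr_length Control-region length in bp (e.g. 1122 in humans).
#' @param genome_length Mitochondrial genome length in bp (e.g. 16569).
#' @param digits Decimal places for the reported percent (default 2).
#' @return Percent of the genome, e.g. 6.77 for the human control region.
#' @export
cr_fraction <- function(cr_length, genome_length, digits = 2L) {
  round(100 * cr_length / genome_length, digits)
}
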