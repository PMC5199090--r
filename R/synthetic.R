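# Synthetic control-region alignment generator with known ground truth:
# hypervariable blocks, clade structure, transition bias, configured indels
# and a diagnostic species deletion.

#' Configuration for the synthetic alignment generator
#'
#' Sequences evolve down a star-of-stars genealogy: a random ancestral
#' sequence gives rise to one deeply diverged outgroup ancestor and one
#' ancestor per clade; every haplotype is then an independent draw from its
#' clade ancestor.  Per-site substitution probabilities are multiplied by
#' the rate multiplier of any hypervariable block covering the site, and
#' substitutions are drawn with a 4:1 transition:transversion weight so
#' that p- and K2P distances differ measurably.  Indels are placed only at
#' configured positions (no random indel process), appearing as gap columns
#' in the carrier clades; the default is a single 15-column diagnostic
#' deletion near the right end carried by the first two clades.
#'
#' @param n_cols Alignment width (default 1020).
#' @param clades Named integer vector: haplotypes per clade (default four
#'   clades of nine).
#' @param clade_divergence Per-site substitution probability on each clade's
#'   ancestral branch (recycled over clades; default 0.01).
#' @param tip_divergence Per-site substitution probability on each
#'   haplotype's terminal branch (default 0.005).
#' @param blocks List of `c(start, end, multiplier)` hypervariable blocks;
#'   default one dominant left-domain block, columns 1-380 at 8x.
#' @param ts_tv_weight Transition:transversion draw weight (default 4).
#' @param indels List of `list(start, length, clades)` fixed indels; default
#'   one 15-column deletion at columns 986-1000 carried by the first two
#'   clades (the "bornean-like" clades).
#' @param n_outgroup Outgroup sequences (default 2).
#' @param outgroup_divergence Per-site substitution probability on the
#'   outgroup ancestral branch (default 0.08).
#' @return An object of class `cr_synconfig`.
#' @export
syn_config <- function(n_cols = 1020L,
                       clades = c(CL1 = 9L, CL2 = 9L, CL3 = 9L, CL4 = 9L),
                       clade_divergence = 0.01,
                       tip_divergence = 0.005,
                       blocks = list(c(1L, 380L, 8)),
                       ts_tv_weight = 4,
                       indels = NULL,
                       n_outgroup = 2L,
                       outgroup_divergence = 0.08) {
  n_cols <- as.integer(n_cols)
  if (n_cols < 1L) stop("config error: n_cols must be positive", call. = FALSE)
  if (is.null(names(clades)) || any(!nzchar(names(clades)))) {
    stop("config error: clades must be named", call. = FALSE)
  }
  if (any(clades < 1L)) stop("config error: each clade needs >= 1 haplotype", call. = FALSE)
  clade_divergence <- rep_len(clade_divergence, length(clades))
  if (any(clade_divergence < 0) || tip_divergence < 0 || outgroup_divergence < 0) {
    stop("config error: divergences must be non-negative", call. = FALSE)
  }
  blocks <- lapply(blocks, function(b) {
    b <- as.numeric(b)
    if (length(b) != 3L || b[1L] < 1L || b[2L] > n_cols || b[1L] > b[2L] || b[3L] <= 0) {
      stop("config error: each block must be c(start, end, multiplier) within bounds",
           call. = FALSE)
    }
    b
  })
  if (length(blocks) > 1L) {
    bs <- do.call(rbind, blocks)
    bs <- bs[order(bs[, 1L]), , drop = FALSE]
    if (any(bs[-1L, 1L] <= bs[-nrow(bs), 2L])) {
      stop("config error: blocks overlap", call. = FALSE)
    }
  }
  if (is.null(indels)) {
    carriers <- names(clades)[seq_len(min(2L, length(clades)))]
    indels <- list(list(start = n_cols - 34L, length = 15L, clades = carriers))
  }
  indels <- lapply(indels, function(idl) {
    if (idl$length >= n_cols || idl$start < 1L || idl$start + idl$length - 1L > n_cols) {
      stop("config error: indel exceeds sequence bounds", call. = FALSE)
    }
    if (!all(idl$clades %in% names(clades))) {
      stop("config error: indel carrier clade not defined", call. = FALSE)
    }
    idl
  })
  structure(list(n_cols = n_cols, clades = clades,
                 clade_divergence = stats::setNames(clade_divergence, names(clades)),
                 tip_divergence = tip_divergence,
                 blocks = blocks, ts_tv_weight = ts_tv_weight,
                 indels = indels, n_outgroup = as.integer(n_outgroup),
                 outgroup_divergence = outgroup_divergence),
            class = "cr_synconfig")
}

# Per-column rate multipliers from the block list.
block_multipliers <- function(config) {
  mult <- rep(1, config$n_cols)
  for (b in config$blocks) mult[b[1L]:b[2L]] <- b[3L]
  mult
}

# Mutate a character vector of bases with per-site probability p * mult,
# transition-biased; probabilities are capped at 0.75.
mutate_sequence <- function(x, p, mult, ts_tv_weight) {
  prob <- pmin(p * mult, 0.75)
  hit <- which(stats::runif(length(x)) < prob)
  if (length(hit) == 0L) return(x)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  p_ts <- ts_tv_weight / (ts_tv_weight + 2)
  is_ts <- stats::runif(length(hit)) < p_ts
  new <- character(length(hit))
  new[is_ts] <- transition[x[hit[is_ts]]]
  if (any(!is_ts)) {
    tv <- hit[!is_ts]
    pick <- stats::runif(length(tv)) < 0.5
    new[!is_ts] <- mapply(function(base, first) transversions[[base]][if (first) 1L else 2L],
                          x[tv], pick)
  }
  x[hit] <- new
  x
}

#' Generate a synthetic control-region alignment with ground truth
#'
#' @param config A [syn_config()].
#' @param seed Integer seed; the same config and seed always produce
#'   byte-identical output.
#' @return List with `alignment` (a [cr_alignment]) and `truth`: a list
#'   carrying `labels` (data frame id/clade/is_outgroup), `blocks`
#'   (data frame start/end/multiplier), `indel_carriers` (id -> logical per
#'   indel, as a list of character vectors of carrier ids) and the `config`.
#' @export
generate_alignment <- function(config = syn_config(), seed = 1L) {
  stopifnot(inherits(config, "cr_synconfig"))
  set.seed(as.integer(seed))
  mult <- block_multipliers(config)
  root <- sample(.DNA_STATES, config$n_cols, replace = TRUE)
  seqs <- list()
  labels <- list()
  for (ci in seq_along(config$clades)) {
    cname <- names(config$clades)[ci]
    anc <- mutate_sequence(root, config$clade_divergence[ci], mult, config$ts_tv_weight)
    for (hi in seq_len(config$clades[ci])) {
      id <- sprintf("%s_%02d", cname, hi)
      seqs[[id]] <- mutate_sequence(anc, config$tip_divergence, mult, config$ts_tv_weight)
      labels[[id]] <- cname
    }
  }
  if (config$n_outgroup > 0L) {
    og_anc <- mutate_sequence(root, config$outgroup_divergence, mult, config$ts_tv_weight)
    for (oi in seq_len(config$n_outgroup)) {
      id <- sprintf("OG%d", oi)
      seqs[[id]] <- mutate_sequence(og_anc, config$tip_divergence, mult, config$ts_tv_weight)
      labels[[id]] <- NA_character_
    }
  }
  carriers <- list()
  for (ii in seq_along(config$indels)) {
    idl <- config$indels[[ii]]
    cols <- idl$start:(idl$start + idl$length - 1L)
    ids <- names(labels)[vapply(labels, function(l) !is.na(l) && l %in% idl$clades,
                                logical(1))]
    for (id in ids) seqs[[id]][cols] <- "-"
    carriers[[ii]] <- ids
  }
  aln <- cr_alignment(vapply(seqs, paste, character(1), collapse = ""))
  truth <- list(
    labels = data.frame(id = names(labels),
                        clade = unlist(labels, use.names = FALSE),
                        is_outgroup = is.na(unlist(labels, use.names = FALSE)),
                        stringsAsFactors = FALSE),
    blocks = do.call(rbind, lapply(config$blocks, function(b) {
      data.frame(start = b[1L], end = b[2L], multiplier = b[3L])
    })),
    indel_carriers = carriers,
    config = config)
  list(alignment = aln, truth = truth)
}

#' Write generator ground truth as JSON
#'
#' @param truth The `truth` element of a [generate_alignment()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(labels = truth$labels, blocks = truth$blocks,
         indel_carriers = truth$indel_carriers),
    path, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
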