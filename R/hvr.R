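# Sliding-window diversity profiles and delimitation of conserved versus
# hypervariable regions.

#' Sliding-window diversity profile
#'
#' Windows are anchored at column 1 and advance by `step`; no partial
#' trailing window is emitted, so the number of windows is
#' `floor((n_cols - window_length) / step) + 1`.  Within each window the
#' per-site diversity `pi` is the mean pairwise difference count over the
#' window's analysed columns divided by the number of analysed columns;
#' windows with no analysed column carry `pi = 0` and are flagged.
#'
#' @param aln A [cr_alignment] with at least 2 records.
#' @param window_length Window width in columns (default 100).
#' @param step Step size in columns (default 25).
#' @param policy A [gap_policy()]; the published profile convention
#'   excludes gap-containing sites, i.e. `complete_deletion`.
#' @return A data frame of class `cr_window_profile` with columns `start`,
#'   `end`, `midpoint`, `n_analyzed`, `S`, `eta`, `n_pair_diffs` (total of
#'   per-pair difference counts in the window), `pi` and `empty` (flag);
#'   window geometry and totals are stored as attributes.
#' @export
window_profile <- function(aln, window_length = 100L, step = 25L,
                           policy = "complete_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  if (nrow(aln) < 2L) stop("at least 2 records are required", call. = FALSE)
  policy <- gap_policy(policy)
  n_cols <- ncol(aln)
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length > n_cols) {
    stop(sprintf("window length %d exceeds the %d alignment columns",
                 window_length, n_cols), call. = FALSE)
  }
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  sites <- analyzed_sites(aln, policy)
  cs <- column_stats(aln, sites, policy)
  n_pairs <- choose(nrow(aln), 2L)
  # per-column vectors over the full alignment width
  seg_col <- numeric(n_cols); seg_col[sites] <- as.numeric(cs$n_states >= 2L)
  eta_col <- numeric(n_cols); eta_col[sites] <- pmax(cs$n_states - 1L, 0L)
  diff_col <- numeric(n_cols); diff_col[sites] <- cs$n_pair_diffs
  ana_col <- numeric(n_cols); ana_col[sites] <- 1
  starts <- seq(1L, n_cols - window_length + 1L, by = step)
  win <- function(v) vapply(starts, function(s) sum(v[s:(s + window_length - 1L)]),
                            numeric(1))
  n_ana <- win(ana_col)
  S_w <- win(seg_col)
  eta_w <- win(eta_col)
  d_w <- win(diff_col)
  pi_w <- ifelse(n_ana > 0, (d_w / n_pairs) / n_ana, 0)
  df <- data.frame(start = starts,
                   end = starts + window_length - 1L,
                   midpoint = starts + (window_length - 1L) / 2,
                   n_analyzed = as.integer(n_ana),
                   S = as.integer(S_w),
                   eta = as.integer(eta_w),
                   n_pair_diffs = d_w,
                   pi = pi_w,
                   empty = n_ana == 0)
  structure(df,
            class = c("cr_window_profile", "data.frame"),
            window_length = window_length, step = step, policy = policy,
            n_cols = n_cols, n_records = nrow(aln),
            S_total = sum(seg_col), n_sites_total = sum(ana_col))
}

#' Expected per-window count of segregating sites
#'
#' Under uniform scatter of the `S` observed segregating sites over the
#' analysed columns, a window of `window_length` analysed sites is expected
#' to contain `S * window_length / n_sites_analyzed` of them.  This
#' expectation is the conservation threshold against which windows are
#' classified; callers may scale it with a multiplier.
#'
#' @param aln A [cr_alignment] with at least 2 records.
#' @param window_length Window width in columns.
#' @param policy A [gap_policy()].
#' @return Expected segregating-site count per window (numeric).
#' @export
conservation_threshold <- function(aln, window_length = 100L,
                                   policy = "complete_deletion") {
  seg <- segregating_sites(aln, policy)
  n_sites <- length(analyzed_sites(aln, policy))
  if (n_sites == 0L) return(0)
  seg$S * window_length / n_sites
}

#' Delimit conserved and hypervariable regions from a window profile
#'
#' Each window is classified hypervariable iff its observed segregating-site
#' count exceeds `threshold_multiplier` times its expected count under
#' uniform scatter (the expectation is scaled by the window's analysed-site
#' count, reducing to `S * window_length / n_sites` on gap-free data).  A
#' column is labelled hypervariable iff a strict majority of the windows
#' covering it are hypervariable (ties conserved), and maximal runs of
#' equal-label columns form the reported intervals.  The leftmost
#' hypervariable interval is flagged `HVRI`.
#'
#' @param profile A [window_profile()] result.
#' @param aln The alignment the profile was computed on.
#' @param threshold_multiplier Scale factor on the expected count
#'   (default 1).
#' @return A data frame of class `cr_regions` with columns `start`, `end`,
#'   `label` (`conserved`/`hypervariable`) and `hvri` (logical); the
#'   threshold used is stored as attribute `threshold_used`.
#' @export
delimit_regions <- function(profile, aln, threshold_multiplier = 1) {
  stopifnot(inherits(profile, "cr_window_profile"), inherits(aln, "cr_alignment"))
  if (nrow(profile) == 0L) stop("empty window profile", call. = FALSE)
  wl <- attr(profile, "window_length")
  n_cols <- attr(profile, "n_cols")
  S_total <- attr(profile, "S_total")
  n_sites_total <- attr(profile, "n_sites_total")
  expected <- if (n_sites_total > 0) S_total * profile$n_analyzed / n_sites_total else
    rep(0, nrow(profile))
  hyper_win <- profile$S > threshold_multiplier * expected
  # column vote: a column is hypervariable iff a strict majority of the
  # windows covering it are hypervariable
  cover <- integer(n_cols)
  hyper_votes <- integer(n_cols)
  for (i in seq_len(nrow(profile))) {
    idx <- profile$start[i]:profile$end[i]
    cover[idx] <- cover[idx] + 1L
    if (hyper_win[i]) hyper_votes[idx] <- hyper_votes[idx] + 1L
  }
  covered <- which(cover > 0L)
  lab <- ifelse(hyper_votes[covered] * 2L > cover[covered], "hypervariable", "conserved")
  # merge runs
  breaks <- which(diff(covered) != 1L | lab[-1L] != lab[-length(lab)])
  starts <- covered[c(1L, breaks + 1L)]
  ends <- covered[c(breaks, length(covered))]
  labels <- lab[c(1L, breaks + 1L)]
  df <- data.frame(start = starts, end = ends, label = labels,
                   stringsAsFactors = FALSE)
  df$hvri <- FALSE
  first_hv <- which(df$label == "hypervariable")[1L]
  if (!is.na(first_hv)) df$hvri[first_hv] <- TRUE
  structure(df, class = c("cr_regions", "data.frame"),
            threshold_used = threshold_multiplier *
              (if (n_sites_total > 0) S_total * wl / n_sites_total else 0),
            threshold_multiplier = threshold_multiplier,
            window_length = wl, step = attr(profile, "step"))
}

#' Convert region intervals to reference coordinates
#'
#' Interval endpoints are snapped inward to the nearest mapped reference
#' position (gap columns of the reference are unmapped); intervals that do
#' not intersect the mapped image are dropped.
#'
#' @param regions A [delimit_regions()] result.
#' @param cmap A [build_coordinate_map()] result.
#' @return Data frame with `ref_start`, `ref_end`, `label`, `hvri`.
#' @export
regions_to_reference <- function(regions, cmap) {
  stopifnot(inherits(regions, "cr_regions"), inherits(cmap, "cr_coordmap"))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    inside <- cmap$columns >= regions$start[i] & cmap$columns <= regions$end[i]
    if (!any(inside)) return(NULL)
    data.frame(ref_start = min(cmap$refpos[inside]),
               ref_end = max(cmap$refpos[inside]),
               label = regions$label[i], hvri = regions$hvri[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a window profile as TSV
#'
#' @param profile A [window_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "cr_window_profile"))
  df <- profile[, c("start", "midpoint", "n_analyzed", "S", "pi")]
  names(df) <- c("start", "midpoint", "n_analyzed_sites", "S_window", "pi_window")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write delimited regions as TSV
#'
#' Coordinates are written 1-based inclusive.
#'
#' @param regions A [delimit_regions()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  stopifnot(inherits(regions, "cr_regions"))
  utils::write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a window diversity profile
#'
#' Midpoint-versus-pi polyline, optionally shading delimited hypervariable
#' intervals.
#'
#' @param x A [window_profile()] result.
#' @param regions Optional [delimit_regions()] result to shade.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cr_window_profile <- function(x, regions = NULL, ...) {
  graphics::plot(x$midpoint, x$pi, type = "l", xlab = "alignment position",
                 ylab = expression(pi), ...)
  if (!is.null(regions)) {
    hv <- regions[regions$label == "hypervariable", , drop = FALSE]
    if (nrow(hv)) {
      usr <- graphics::par("usr")
      graphics::rect(hv$start, usr[3L], hv$end, usr[4L],
                     col = grDevices::adjustcolor("firebrick", 0.15), border = NA)
    }
  }
  invisible(x)
}
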