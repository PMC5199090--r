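# Scalar diversity indices: haplotypes h, segregating sites S, total
# mutations eta, mean pairwise differences k, per-site diversity pi.

#' Gap-handling policies
#'
#' Diversity statistics depend on how alignment gaps and missing data are
#' treated:
#' \describe{
#'   \item{complete_deletion}{every column containing a gap or `N` is removed
#'     before any computation (the default for tabulated scalar statistics:
#'     the number of analysed sites is then smaller than the alignment
#'     length whenever indels are present);}
#'   \item{pairwise_deletion}{gaps and `N` are missing data, dropped per
#'     column for site statistics and per pair for pairwise differences;}
#'   \item{include_gaps}{`-` is an ordinary fifth state (an indel
#'     difference counts), while `N` remains missing.}
#' }
#'
#' @param policy Policy name (partial matching allowed).
#' @return The matched policy string.
#' @export
gap_policy <- function(policy = c("complete_deletion", "pairwise_deletion", "include_gaps")) {
  match.arg(policy)
}

# States counted at a column under a policy.
counted_states_set <- function(policy) {
  if (policy == "include_gaps") c(.DNA_STATES, "-") else .DNA_STATES
}

#' Analysed columns of an alignment under a gap policy
#'
#' Under `complete_deletion` these are the columns free of gaps and `N`;
#' under the other policies, the columns where at least two records carry a
#' counted (non-missing) state, so that at least one pair is comparable.
#'
#' @param aln A [cr_alignment].
#' @param policy A [gap_policy()].
#' @return Integer vector of 1-based column indices.
#' @export
analyzed_sites <- function(aln, policy = "complete_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  policy <- gap_policy(policy)
  counted <- counted_states_set(policy)
  if (policy == "complete_deletion") {
    which(apply(aln, 2L, function(col) all(col %in% .DNA_STATES)))
  } else {
    which(apply(aln, 2L, function(col) sum(col %in% counted) >= 2L))
  }
}

# Per-column counted-state tallies: list(n_states, n_pair_diffs) vectors over
# the given columns.  n_pair_diffs at a column is the number of unordered
# record pairs that are comparable there and differ, which summed over
# columns equals the total of per-pair difference counts.
column_stats <- function(aln, columns, policy) {
  counted <- counted_states_set(policy)
  n_states <- integer(length(columns))
  n_diffs <- numeric(length(columns))
  for (i in seq_along(columns)) {
    col <- aln[, columns[i]]
    col <- col[col %in% counted]
    tab <- tabulate(match(col, counted), nbins = length(counted))
    present <- tab[tab > 0L]
    n_states[i] <- length(present)
    tot <- sum(present)
    n_diffs[i] <- choose(tot, 2L) - sum(choose(present, 2L))
  }
  list(n_states = n_states, n_pair_diffs = n_diffs)
}

#' Segregating sites and total mutations
#'
#' A column is polymorphic iff at least two distinct counted states occur
#' there; its contribution to the total number of mutations eta is the
#' minimum-mutation count, distinct counted states minus one, so `eta > S`
#' exactly at multi-allelic sites.
#'
#' @param aln A [cr_alignment] with at least 2 records.
#' @param policy A [gap_policy()].
#' @return List with `S` (count of polymorphic sites), `eta` (total number
#'   of mutations) and `sites` (1-based polymorphic column indices).
#' @export
segregating_sites <- function(aln, policy = "complete_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  if (nrow(aln) < 2L) stop("at least 2 records are required", call. = FALSE)
  policy <- gap_policy(policy)
  cols <- analyzed_sites(aln, policy)
  if (length(cols) == 0L) return(list(S = 0L, eta = 0L, sites = integer(0)))
  cs <- column_stats(aln, cols, policy)
  poly <- cs$n_states >= 2L
  list(S = sum(poly),
       eta = sum(pmax(cs$n_states - 1L, 0L)),
       sites = cols[poly])
}

#' Mean number of pairwise nucleotide differences (k)
#'
#' `k` is the average over all unordered record pairs of the number of
#' differing counted sites; under `pairwise_deletion` each pair is compared
#' over its own comparable sites.
#'
#' @param aln A [cr_alignment] with at least 2 records.
#' @param policy A [gap_policy()].
#' @return Mean pairwise difference count (numeric, >= 0).
#' @export
mean_pairwise_differences <- function(aln, policy = "complete_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  if (nrow(aln) < 2L) stop("at least 2 records are required", call. = FALSE)
  policy <- gap_policy(policy)
  cols <- analyzed_sites(aln, policy)
  if (length(cols) == 0L) return(0)
  cs <- column_stats(aln, cols, policy)
  sum(cs$n_pair_diffs) / choose(nrow(aln), 2L)
}

#' Per-pair difference and comparable-site counts
#'
#' @param aln A [cr_alignment].
#' @param policy A [gap_policy()].
#' @return List of two symmetric matrices, `diffs` and `comparable`.
#' @keywords internal
pair_difference_matrix <- function(aln, policy = "complete_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  policy <- gap_policy(policy)
  counted <- counted_states_set(policy)
  n <- nrow(aln)
  cols <- if (policy == "complete_deletion") analyzed_sites(aln, policy) else seq_len(ncol(aln))
  m <- aln[, cols, drop = FALSE]
  diffs <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  comp <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    xi <- m[i, ]
    for (j in (i + 1L):n) {
      xj <- m[j, ]
      ok <- xi %in% counted & xj %in% counted
      d <- sum(xi[ok] != xj[ok])
      diffs[i, j] <- diffs[j, i] <- d
      comp[i, j] <- comp[j, i] <- sum(ok)
    }
  }
  list(diffs = diffs, comparable = comp)
}

#' Summarise the diversity of an alignment
#'
#' Computes, on a single consistent set of analysed columns, the number of
#' haplotypes `h`, the number of polymorphic (segregating) sites `S`, the
#' total number of mutations `eta`, the mean pairwise difference count `k`
#' and the per-site diversity `pi = k / n_sites_analyzed`.
#'
#' @param aln A [cr_alignment] with at least 2 records.
#' @param policy A [gap_policy()].
#' @return An object of class `cr_diversity`: list with `n_records`,
#'   `n_sites_analyzed`, `h`, `S`, `eta`, `k`, `pi`, `policy` and the
#'   analysed `sites`.
#' @export
diversity_summary <- function(aln, policy = "complete_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  if (nrow(aln) < 2L) stop("at least 2 records are required", call. = FALSE)
  policy <- gap_policy(policy)
  cols <- analyzed_sites(aln, policy)
  if (length(cols) == 0L) {
    res <- list(n_records = nrow(aln), n_sites_analyzed = 0L, h = 1L,
                S = 0L, eta = 0L, k = 0, pi = 0, policy = policy, sites = integer(0))
    return(structure(res, class = "cr_diversity"))
  }
  seg <- segregating_sites(aln, policy)
  k <- mean_pairwise_differences(aln, policy)
  hs <- collapse_haplotypes(aln, site_mask = cols,
                            gap_as_state = (policy == "include_gaps"))
  structure(list(n_records = nrow(aln),
                 n_sites_analyzed = length(cols),
                 h = hs$n_haplotypes,
                 S = seg$S,
                 eta = seg$eta,
                 k = k,
                 pi = if (length(cols)) k / length(cols) else 0,
                 policy = policy,
                 sites = cols),
            class = "cr_diversity")
}

#' @export
print.cr_diversity <- function(x, ...) {
  cat(sprintf(
    "<cr_diversity> n = %d, sites = %d (%s)\n  h = %d, S = %d, eta = %d, k = %.3f, pi = %.5f\n",
    x$n_records, x$n_sites_analyzed, x$policy, x$h, x$S, x$eta, x$k, x$pi))
  invisible(x)
}

#' Segment-by-segment diversity table
#'
#' Produces one row per segment in the style of a published diversity table:
#' number of analysed sites, percent of the control region covered,
#' positions, `h`, `S`, `eta` (parenthesised in print convention) and `k`
#' to three decimals.
#'
#' @param aln A full-length [cr_alignment].
#' @param specs List of [segment_spec()] objects (alignment frame).
#' @param policy A [gap_policy()].
#' @param path Optional TSV output path.
#' @return Data frame with columns `segment`, `n_sites`, `extent_percent`,
#'   `positions`, `h`, `S`, `eta`, `k`.
#' @export
diversity_table <- function(aln, specs, policy = "complete_deletion", path = NULL) {
  stopifnot(inherits(aln, "cr_alignment"), is.list(specs))
  rows <- lapply(specs, function(sp) {
    sub <- trim_alignment(aln, sp)
    d <- diversity_summary(sub, policy)
    data.frame(segment = sp$name,
               n_sites = d$n_sites_analyzed,
               extent_percent = coverage_percent(sp, aln),
               positions = format_ranges(sp$ranges),
               h = d$h, S = d$S, eta = d$eta,
               k = round(d$k, 3L),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
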