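# Independent brute-force reference implementation of the diversity
# statistics, written as plain nested loops straight from the definitions.
# It deliberately shares no code with the package.

oracle_stats <- function(seqs, policy) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  n <- nrow(m)
  L <- ncol(m)
  ACGT <- c("A", "C", "G", "T")
  counted <- if (policy == "include_gaps") c(ACGT, "-") else ACGT
  missing_states <- if (policy == "include_gaps") "N" else c("N", "-")

  if (policy == "complete_deletion") {
    keep <- logical(L)
    for (c in seq_len(L)) keep[c] <- all(m[, c] %in% ACGT)
    analyzed <- which(keep)
  } else {
    analyzed <- integer(0)
    for (c in seq_len(L)) {
      if (sum(m[, c] %in% counted) >= 2) analyzed <- c(analyzed, c)
    }
  }

  S <- 0L
  eta <- 0L
  for (c in analyzed) {
    states <- unique(m[, c][m[, c] %in% counted])
    if (length(states) >= 2) S <- S + 1L
    eta <- eta + max(length(states) - 1L, 0L)
  }

  total_diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cols <- if (policy == "complete_deletion") analyzed else seq_len(L)
      for (c in cols) {
        a <- m[i, c]; b <- m[j, c]
        if (a %in% counted && b %in% counted && a != b) {
          total_diffs <- total_diffs + 1
        }
      }
    }
  }
  k <- total_diffs / (n * (n - 1) / 2)

  # haplotypes: greedy first-occurrence collapse on the analysed columns,
  # missing states never creating a difference
  h <- 0L
  reps <- list()
  if (length(analyzed) == 0) {
    h <- 1L
  } else {
    for (i in seq_len(n)) {
      x <- m[i, analyzed]
      placed <- FALSE
      for (r in reps) {
        same <- TRUE
        for (c in seq_along(x)) {
          if (!(x[c] %in% missing_states) && !(r[c] %in% missing_states) &&
              x[c] != r[c]) { same <- FALSE; break }
        }
        if (same) { placed <- TRUE; break }
      }
      if (!placed) reps[[length(reps) + 1]] <- x
    }
    h <- length(reps)
  }

  list(h = h, S = S, eta = eta, k = k, n_sites = length(analyzed))
}

# random toy alignment over {A,C,G,T,-,N}: ancestor plus per-sequence
# mutations, with moderate gap/N rates, so columns range from monomorphic
# to multi-allelic
random_toy_alignment <- function(n_records, n_cols, p_mut = 0.3,
                                 p_gap = 0.05, p_n = 0.03) {
  states <- c("A", "C", "G", "T")
  anc <- sample(states, n_cols, replace = TRUE)
  seqs <- vapply(seq_len(n_records), function(i) {
    chars <- anc
    hit <- runif(n_cols) < p_mut
    chars[hit] <- sample(states, sum(hit), replace = TRUE)
    r <- runif(n_cols)
    chars[r < p_gap] <- "-"
    chars[r >= p_gap & r < p_gap + p_n] <- "N"
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("t%02d", seq_len(n_records))
  seqs
}
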