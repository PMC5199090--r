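# Forensic haplotype resolution of marker segments, species classification
# by a diagnostic deletion, and in-silico PCR.

#' Haplotype resolution of a segment
#'
#' Compares the number of haplotypes discerned on a trimmed segment with the
#' number discerned on the full alignment, and lists which full-resolution
#' haplotypes become indistinguishable at segment resolution.
#'
#' @param full_aln The full-length [cr_alignment].
#' @param spec A [segment_spec()] in alignment frame.
#' @param gap_as_state Passed to [collapse_haplotypes()].
#' @return An object of class `cr_resolution`: list with `segment`,
#'   `h_full`, `h_segment`, `discrimination_percent`
#'   (`100 * h_segment / h_full`, unrounded; integer-rounded in reports)
#'   and `collapsed_groups` (each a character vector of representative ids
#'   of >= 2 full haplotypes merged at segment resolution).
#' @export
resolution_report <- function(full_aln, spec, gap_as_state = TRUE) {
  stopifnot(inherits(full_aln, "cr_alignment"), inherits(spec, "cr_segment"))
  hs_full <- collapse_haplotypes(full_aln, gap_as_state = gap_as_state)
  seg_aln <- trim_alignment(full_aln, spec)
  hs_seg <- collapse_haplotypes(seg_aln, gap_as_state = gap_as_state)
  # every member of a full haplotype carries an identical sequence, hence an
  # identical segment string, so the full -> segment haplotype map is
  # well-defined through any member
  full_rep <- vapply(hs_full$haplotypes, function(h) h$members[[1L]], character(1))
  seg_of_full <- hs_seg$assignment[full_rep]
  groups <- split(full_rep, seg_of_full)
  collapsed <- unname(groups[vapply(groups, length, integer(1)) >= 2L])
  structure(list(segment = spec$name,
                 h_full = hs_full$n_haplotypes,
                 h_segment = hs_seg$n_haplotypes,
                 discrimination_percent = 100 * hs_seg$n_haplotypes / hs_full$n_haplotypes,
                 collapsed_groups = collapsed),
            class = "cr_resolution")
}

#' @export
print.cr_resolution <- function(x, ...) {
  cat(sprintf("<cr_resolution> segment %s: %d / %d haplotypes discerned (%d%%)\n",
              x$segment, x$h_segment, x$h_full, round(x$discrimination_percent)))
  if (length(x$collapsed_groups)) {
    cat(sprintf("  %d group(s) of full haplotypes merged at segment resolution\n",
                length(x$collapsed_groups)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Diagnostic-deletion species classification

#' Locate a diagnostic deletion by comparing two aligned reference sequences
#'
#' Given a reference control region carrying the locus and one carrying the
#' deletion, aligned to each other (equal length, gaps allowed), finds the
#' deleted stretch as the longest run of columns that are gaps in
#' `ref_without` but bases in `ref_with`, and records the 12-mers flanking
#' the locus on the degapped carrier-free reference, used to detect the
#' locus in (unaligned) query sequences.
#'
#' @param ref_with Aligned reference sequence containing the locus.
#' @param ref_without Aligned reference sequence carrying the deletion;
#'   must have the same aligned length as `ref_with`.
#' @param min_length Minimum run length accepted as the locus (default 10).
#' @return List with `start`, `length` (degapped `ref_with` coordinates),
#'   `left_flank` and `right_flank` (12-mers adjacent to the locus).
#' @export
find_deletion_locus <- function(ref_with, ref_without, min_length = 10L) {
  a <- strsplit(toupper(ref_with), "")[[1L]]
  b <- strsplit(toupper(ref_without), "")[[1L]]
  if (length(a) != length(b)) {
    stop("references must be aligned to each other (equal length)", call. = FALSE)
  }
  is_del <- b == "-" & a != "-"
  if (!any(is_del)) stop("no deletion found between the references", call. = FALSE)
  r <- rle(is_del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  if (r$lengths[best] < min_length) {
    stop(sprintf("longest candidate deletion run (%d columns) is shorter than min_length = %d",
                 r$lengths[best], min_length), call. = FALSE)
  }
  del_cols <- starts[best]:ends[best]
  # degapped coordinates on ref_with
  a_pos <- cumsum(a != "-")
  start <- a_pos[del_cols[1L]]
  del_len <- sum(a[del_cols] != "-")
  a_clean <- a[a != "-"]
  if (start < 13L || length(a_clean) - (start + del_len - 1L) < 12L) {
    stop("deletion locus too close to a sequence end for 12-mer flanks", call. = FALSE)
  }
  list(start = start, length = del_len,
       left_flank = paste(a_clean[(start - 12L):(start - 1L)], collapse = ""),
       right_flank = paste(a_clean[(start + del_len):(start + del_len + 11L)], collapse = ""))
}

# Hamming-distance hits of `query` along `subject`; both plain ACGT strings.
# Returns data.frame(start, mismatches) of all hits with <= max_mm, or of
# the minimal-mismatch stratum if best_only.
hamming_hits <- function(subject, query, max_mm = 0L, best_only = TRUE) {
  s <- strsplit(subject, "")[[1L]]
  q <- strsplit(query, "")[[1L]]
  m <- length(q)
  L <- length(s)
  if (L < m) return(data.frame(start = integer(0), mismatches = integer(0)))
  starts <- seq_len(L - m + 1L)
  mm <- vapply(starts, function(p) sum(s[p:(p + m - 1L)] != q), integer(1))
  hit <- which(mm <= max_mm)
  if (length(hit) && best_only) hit <- hit[mm[hit] == min(mm[hit])]
  data.frame(start = starts[hit], mismatches = mm[hit])
}

#' Classify a control-region sequence by the diagnostic deletion
#'
#' A consistent 15 bp deletion towards the right end of the Bornean
#' orang-utan control region separates the two species' sequence lengths
#' (Bornean 999-1000 bp versus Sumatran 1011-1016 bp).  Locus detection by
#' flanking 12-mers (up to 2 mismatches per flank) is primary; the degapped
#' length, split at the 1005/1006 bp midpoint of the printed ranges, is the
#' fallback when the flanks cannot be located.
#'
#' @param seq A sequence string (gaps allowed; classified on the degapped
#'   sequence, which must be 950-1100 bp long).
#' @param locus Optional [find_deletion_locus()] result derived from one
#'   reference carrying the locus and one carrying the deletion; when
#'   absent, only the length fallback applies.
#' @param length_boundary Degapped length at and below which a sequence is
#'   deletion-plausible (default 1005).
#' @return One of `"bornean-like"`, `"sumatran-like"`, `"indeterminate"`.
#' @export
classify_species_by_deletion <- function(seq, locus = NULL,
                                         length_boundary = 1005L) {
  q <- degap(canonicalise_sequence(seq))
  len <- nchar(q)
  if (len < 950L || len > 1100L) {
    stop(sprintf("input error: degapped length %d outside the plausible control-region window [950, 1100]",
                 len), call. = FALSE)
  }
  locus_state <- NA  # TRUE present, FALSE absent, NA undetectable
  if (!is.null(locus)) {
    lf <- hamming_hits(q, locus$left_flank, max_mm = 2L)
    rf <- hamming_hits(q, locus$right_flank, max_mm = 2L)
    if (nrow(lf) == 1L && nrow(rf) == 1L) {
      inner <- rf$start - (lf$start + 12L)
      if (inner >= 0L) locus_state <- inner >= ceiling(locus$length / 2)
    }
  }
  if (!is.na(locus_state)) {
    if (!locus_state) return("bornean-like")
    if (len >= length_boundary + 1L) return("sumatran-like")
    warning("locus present but degapped length is deletion-sized; classification indeterminate")
    return("indeterminate")
  }
  if (len <= length_boundary) "bornean-like" else "sumatran-like"
}

# ---------------------------------------------------------------------------
# In-silico PCR

#' Built-in amplification and sequencing primers
#'
#' The control-region amplification pair anneals to the cytochrome b and
#' 12S rRNA genes on opposite sides of the control region, producing a
#' single large (~1.6 kb) amplicon; the two internal primers are used for
#' primer walking.
#'
#' @return Named list of primer sequences (5' to 3').
#' @export
builtin_primers <- function() {
  list(CYTBMIDF = "CAATCCTACGATCCGTCCCC",
       `133R` = "CGGGGATGCTTGCATGTGTAAC",
       CRMIDF = "CCCCTCAGTTAGTGGTCCCT",
       CRMIDR = "GGAGCGAGGAGAGTAGCACT")
}

#' Define a primer pair
#'
#' @param forward,reverse Primer sequences, 5' to 3', over `{A,C,G,T}`,
#'   at least 15 bases.
#' @param names Optional character vector of length 2 with primer names.
#' @return An object of class `cr_primer_pair`.
#' @export
primer_pair <- function(forward, reverse, names = c("fwd", "rev")) {
  check <- function(p, nm) {
    p <- toupper(p)
    if (!grepl("^[ACGT]+$", p)) stop(sprintf("primer %s contains non-ACGT characters", nm),
                                     call. = FALSE)
    if (nchar(p) < 15L) stop(sprintf("primer %s shorter than 15 bases", nm), call. = FALSE)
    p
  }
  structure(list(forward = check(forward, names[1L]),
                 reverse = check(reverse, names[2L]),
                 names = names),
            class = "cr_primer_pair")
}

#' Reverse complement
#' @param x A DNA string over `{A,C,G,T,N,-}`.
#' @return The reverse complement.
#' @export
reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

#' In-silico PCR on a template sequence
#'
#' Finds the unique best forward-primer hit on the plus strand and the
#' unique best reverse-primer hit (as the reverse complement, downstream of
#' the forward hit), with a Hamming-only mismatch model: indels are not
#' modelled and the three 3'-terminal bases of each primer must match
#' exactly at any mismatch setting.  The predicted product runs from the
#' forward primer's 5' base to the reverse primer's 5' base inclusive.
#'
#' @param template A sequence string (degapped internally).
#' @param pair A [primer_pair()].
#' @param max_mismatches Maximum mismatches per primer outside the
#'   3'-terminal bases (default 0).
#' @param product_range Plausible product lengths; predictions outside it
#'   fail, flagging a wrong-species template or numt-like paralogue.
#' @return An object of class `cr_amplicon`: list with `forward_start`,
#'   `reverse_end` (template coordinates on the plus strand),
#'   `product_length` and `product` (sequence including both primers).
#' @export
in_silico_pcr <- function(template, pair, max_mismatches = 0L,
                          product_range = c(200L, 5000L)) {
  stopifnot(inherits(pair, "cr_primer_pair"))
  tmpl <- degap(canonicalise_sequence(template, "template"))
  fwd <- pair$forward
  rev_rc <- reverse_complement(pair$reverse)
  best_unique <- function(hits, primer_name) {
    if (nrow(hits) == 0L) {
      stop(sprintf("no-hit failure: primer %s not found on the template", primer_name),
           call. = FALSE)
    }
    if (nrow(hits) > 1L) {
      stop(sprintf("ambiguous-hit failure: primer %s has %d equally good sites",
                   primer_name, nrow(hits)), call. = FALSE)
    }
    hits
  }
  exact_3prime <- function(hits, primer, where) {
    if (nrow(hits) == 0L) return(hits)
    m <- nchar(primer)
    keep <- vapply(hits$start, function(p) {
      if (where == "last3") {
        substr(tmpl, p + m - 3L, p + m - 1L) == substr(primer, m - 2L, m)
      } else {
        substr(tmpl, p, p + 2L) == substr(primer, 1L, 3L)
      }
    }, logical(1))
    hits[keep, , drop = FALSE]
  }
  # the reverse primer's 3' end maps to the start of its reverse-complement
  # match on the plus strand, hence "first3" exactness there
  fhits <- exact_3prime(hamming_hits(tmpl, fwd, max_mismatches), fwd, "last3")
  fhit <- best_unique(fhits, pair$names[1L])
  rhits <- exact_3prime(hamming_hits(tmpl, rev_rc, max_mismatches), rev_rc, "first3")
  rhits <- rhits[rhits$start > fhit$start, , drop = FALSE]
  rhit <- best_unique(rhits, pair$names[2L])
  product_end <- rhit$start + nchar(rev_rc) - 1L
  len <- product_end - fhit$start + 1L
  if (len < product_range[1L] || len > product_range[2L]) {
    stop(sprintf("implausible product length %d bp (outside [%d, %d]); wrong-species template or numt-like paralogue suspected",
                 len, product_range[1L], product_range[2L]), call. = FALSE)
  }
  structure(list(forward_start = fhit$start,
                 reverse_end = product_end,
                 forward_mismatches = fhit$mismatches,
                 reverse_mismatches = rhit$mismatches,
                 product_length = len,
                 product = substr(tmpl, fhit$start, product_end)),
            class = "cr_amplicon")
}

#' @export
print.cr_amplicon <- function(x, ...) {
  cat(sprintf("<cr_amplicon> %d bp product, template positions %d-%d\n",
              x$product_length, x$forward_start, x$reverse_end))
  invisible(x)
}
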