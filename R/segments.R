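# Named coordinate segments: trimming, excision and the built-in registry of
# control-region marker segments used by earlier orang-utan studies.

#' Define a named coordinate segment
#'
#' A segment is one or more sorted, non-overlapping, 1-based inclusive
#' ranges on either alignment columns or reference positions.
#'
#' @param name Segment name.
#' @param ranges Two-column matrix (start, end) or list of length-2 vectors.
#' @param frame Coordinate frame: `"alignment"` columns or `"reference"`
#'   positions (converted via [spec_to_alignment()]).
#' @param citation Optional free-text provenance for built-in segments.
#' @param estimated Logical; TRUE where the coordinates are estimates for
#'   unpublished sequences rather than published positions.
#' @return An object of class `cr_segment`.
#' @export
segment_spec <- function(name, ranges, frame = c("alignment", "reference"),
                         citation = NULL, estimated = FALSE) {
  frame <- match.arg(frame)
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.integer(ranges), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  if (nrow(ranges) == 0L) stop("segment must contain at least one range", call. = FALSE)
  if (any(ranges[, "start"] > ranges[, "end"]) || any(ranges < 1L)) {
    stop(sprintf("invalid range in segment '%s'", name), call. = FALSE)
  }
  o <- order(ranges[, "start"])
  ranges <- ranges[o, , drop = FALSE]
  if (nrow(ranges) > 1L &&
      any(ranges[-1L, "start"] <= ranges[-nrow(ranges), "end"])) {
    stop(sprintf("overlapping ranges in segment '%s'", name), call. = FALSE)
  }
  structure(list(name = name, ranges = ranges, frame = frame,
                 citation = citation, estimated = isTRUE(estimated)),
            class = "cr_segment")
}

#' @export
print.cr_segment <- function(x, ...) {
  cat(sprintf("<cr_segment> %s [%s frame]: %s (%d columns)%s\n",
              x$name, x$frame, format_ranges(x$ranges), segment_length(x),
              if (x$estimated) " [estimated]" else ""))
  invisible(x)
}

#' Format ranges in zero-padded inclusive style
#' @param ranges Two-column (start, end) matrix.
#' @return A string such as `"001-032; 356-999"`.
#' @keywords internal
format_ranges <- function(ranges) {
  paste(sprintf("%03d-%03d", ranges[, 1L], ranges[, 2L]), collapse = "; ")
}

#' Total length of a segment
#' @param spec A [segment_spec()].
#' @return Number of positions covered.
#' @export
segment_length <- function(spec) {
  stopifnot(inherits(spec, "cr_segment"))
  sum(spec$ranges[, "end"] - spec$ranges[, "start"] + 1L)
}

#' Columns covered by a segment
#' @param spec A [segment_spec()] in alignment frame.
#' @param n_cols Number of alignment columns, for bounds checking.
#' @return Sorted integer vector of covered columns.
#' @export
segment_columns <- function(spec, n_cols) {
  stopifnot(inherits(spec, "cr_segment"))
  if (spec$frame != "alignment") {
    stop(sprintf("segment '%s' is in the reference frame; convert with spec_to_alignment()",
                 spec$name), call. = FALSE)
  }
  if (any(spec$ranges[, "end"] > n_cols)) {
    stop(sprintf("range error: segment '%s' (%s) exceeds the %d alignment columns",
                 spec$name, format_ranges(spec$ranges), n_cols), call. = FALSE)
  }
  unlist(lapply(seq_len(nrow(spec$ranges)),
                function(i) spec$ranges[i, 1L]:spec$ranges[i, 2L]),
         use.names = FALSE)
}

#' Trim an alignment to a segment
#'
#' Returns the column-concatenation of the segment's ranges, record order
#' preserved.
#'
#' @param aln A [cr_alignment].
#' @param spec A [segment_spec()] in alignment frame.
#' @return A [cr_alignment] with `segment_length(spec)` columns.
#' @export
trim_alignment <- function(aln, spec) {
  stopifnot(inherits(aln, "cr_alignment"))
  subset_columns(aln, segment_columns(spec, ncol(aln)))
}

#' Excise a segment and concatenate the remainder
#'
#' Removes the segment's columns and concatenates all remaining alignment
#' columns in order (the complement is computed on the alignment frame).
#'
#' @param aln A [cr_alignment].
#' @param spec A [segment_spec()] in alignment frame.
#' @return A [cr_alignment] of the complementary columns.
#' @export
excise_and_concatenate <- function(aln, spec) {
  stopifnot(inherits(aln, "cr_alignment"))
  keep <- setdiff(seq_len(ncol(aln)), segment_columns(spec, ncol(aln)))
  if (length(keep) == 0L) {
    stop(sprintf("segment '%s' covers the whole alignment; the remainder is empty",
                 spec$name), call. = FALSE)
  }
  subset_columns(aln, keep)
}

#' Complement of a segment as a segment
#'
#' @param spec A [segment_spec()] in alignment frame.
#' @param n_cols Number of alignment columns.
#' @return A [segment_spec()] covering every column not in `spec`.
#' @export
segment_complement <- function(spec, n_cols) {
  keep <- setdiff(seq_len(n_cols), segment_columns(spec, n_cols))
  if (length(keep) == 0L) stop("complement is empty", call. = FALSE)
  breaks <- which(diff(keep) != 1L)
  starts <- keep[c(1L, breaks + 1L)]
  ends <- keep[c(breaks, length(keep))]
  segment_spec(paste0(spec$name, "_remainder"), cbind(starts, ends))
}

#' Percent of the alignment covered by a segment
#'
#' @param spec A [segment_spec()] in alignment frame.
#' @param aln A [cr_alignment], or the number of alignment columns.
#' @param round Round to integer percent (report convention, default TRUE).
#' @return Percent coverage.
#' @export
coverage_percent <- function(spec, aln, round = TRUE) {
  n_cols <- if (inherits(aln, "cr_alignment")) ncol(aln) else as.integer(aln)
  segment_columns(spec, n_cols)  # bounds check
  pct <- 100 * segment_length(spec) / n_cols
  if (round) round(pct) else pct
}

#' Built-in registry of published control-region marker segments
#'
#' The registry carries the left-domain control-region segments analysed in
#' six earlier orang-utan studies, in two coordinate frames: positions on a
#' common all-sequence control-region alignment (authoritative for trimming)
#' and positions on the complete Sumatran mitochondrial genome X97707, where
#' the control region spans positions 15484-16499.  Segments whose source
#' sequences were never published carry `estimated = TRUE`.
#'
#' @return List with elements `alignment` and `reference`, each a named list
#'   of [segment_spec()] objects.
#' @export
segment_registry <- function() {
  aln <- list(
    warren2001 = segment_spec("warren2001", cbind(104L, 381L),
                              citation = "Warren et al. (2001), ~245 bp"),
    jalil_arora = segment_spec("jalil_arora", cbind(33L, 355L),
                               citation = "Jalil et al. (2008); Arora et al. (2010), <=323 bp"),
    nater2013 = segment_spec("nater2013", cbind(1L, 386L),
                             citation = "Nater et al. (2013), <=385 bp"),
    morrogh_bernard2010 = segment_spec("morrogh_bernard2010", cbind(1L, 409L),
                                       citation = "Morrogh-Bernard et al. (2010), <=410 bp",
                                       estimated = TRUE),
    rianti2015 = segment_spec("rianti2015", cbind(1L, 422L),
                              citation = "Rianti et al. (2015), <=422 bp",
                              estimated = TRUE))
  ref <- list(
    warren2001 = segment_spec("warren2001", cbind(15605L, 15844L), frame = "reference",
                              citation = "Warren et al. (2001)"),
    jalil_arora = segment_spec("jalil_arora", cbind(15516L, 15836L), frame = "reference",
                               citation = "Jalil et al. (2008); Arora et al. (2010)"),
    nater2013 = segment_spec("nater2013", cbind(15484L, 15866L), frame = "reference",
                             citation = "Nater et al. (2013)"),
    morrogh_bernard2010 = segment_spec("morrogh_bernard2010", cbind(15484L, 15893L),
                                       frame = "reference",
                                       citation = "Morrogh-Bernard et al. (2010)",
                                       estimated = TRUE),
    rianti2015 = segment_spec("rianti2015", cbind(15484L, 15905L), frame = "reference",
                              citation = "Rianti et al. (2015)", estimated = TRUE),
    control_region = segment_spec("control_region", cbind(15484L, 16499L),
                                  frame = "reference",
                                  citation = "complete control region on X97707"))
  list(alignment = aln, reference = ref)
}

#' Convert a reference-frame segment to alignment columns
#'
#' Endpoints falling on reference positions that are unmapped (outside the
#' coordinate map's image) are snapped inward to the nearest mapped
#' position.
#'
#' @param spec A [segment_spec()] in reference frame.
#' @param cmap A [build_coordinate_map()] result.
#' @return A [segment_spec()] in alignment frame.
#' @export
spec_to_alignment <- function(spec, cmap) {
  stopifnot(inherits(spec, "cr_segment"), inherits(cmap, "cr_coordmap"))
  if (spec$frame != "reference") stop("segment is already in the alignment frame", call. = FALSE)
  if (length(cmap$refpos) == 0L) stop("empty coordinate map", call. = FALSE)
  conv <- function(start, end) {
    lo <- cmap$columns[which(cmap$refpos >= start)[1L]]
    hi_idx <- which(cmap$refpos <= end)
    hi <- cmap$columns[hi_idx[length(hi_idx)]]
    if (is.na(lo) || length(hi) == 0L || lo > hi) {
      stop(sprintf("range error: segment '%s' does not intersect the mapped reference",
                   spec$name), call. = FALSE)
    }
    c(lo, hi)
  }
  ranges <- t(apply(spec$ranges, 1L, function(r) conv(r[1L], r[2L])))
  segment_spec(spec$name, ranges, frame = "alignment",
               citation = spec$citation, estimated = spec$estimated)
}

#' Write a segment registry to JSON
#'
#' @param registry A [segment_registry()]-shaped list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(registry, path) {
  enc <- lapply(registry, function(frame_list) {
    lapply(frame_list, function(sp) {
      list(name = sp$name, frame = sp$frame,
           ranges = apply(sp$ranges, 1L, function(r) list(start = r[1L], end = r[2L])),
           citation = sp$citation, estimated = sp$estimated)
    })
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a segment registry from JSON
#'
#' @param path A file written by [write_registry_json()].
#' @return List of frames, each a named list of [segment_spec()] objects.
#' @export
read_registry_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(frame_list) {
    lapply(frame_list, function(sp) {
      ranges <- do.call(rbind, lapply(sp$ranges, function(r) c(r$start, r$end)))
      segment_spec(sp$name, ranges, frame = sp$frame,
                   citation = sp$citation, estimated = isTRUE(sp$estimated))
    })
  })
}
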