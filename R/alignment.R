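# Sequence I/O, alignment container, coordinate maps and haplotype collapsing.

# IUPAC ambiguity codes collapsed to N on input; N never creates a difference.
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?")
.DNA_STATES <- c("A", "C", "G", "T")

#' Canonicalise a DNA sequence string
#'
#' Upper-cases, converts U to T, collapses IUPAC ambiguity codes to `N`, and
#' rejects any character outside the extended DNA alphabet.
#'
#' @param x A single sequence string.
#' @param id Record identifier used in error messages.
#' @return The canonical sequence over `{A,C,G,T,-,N}`.
#' @keywords internal
canonicalise_sequence <- function(x, id = "<sequence>") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  ok <- chars %in% c(.DNA_STATES, "-", "N", .IUPAC_AMBIG)
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop(sprintf("alphabet error: illegal character '%s' in record '%s' at position %d",
                 chars[pos], id, pos), call. = FALSE)
  }
  chars[chars %in% .IUPAC_AMBIG] <- "N"
  paste(chars, collapse = "")
}

#' Read sequences from a FASTA file
#'
#' Records are returned in file order as a named character vector of
#' canonicalised sequences (upper case, U converted to T, IUPAC ambiguity
#' codes collapsed to `N`).  Duplicate record identifiers are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are record ids.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "acgu"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop(sprintf("parse error in %s: file is empty", path), call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("parse error in %s at line %d: expected '>' header", path, nonblank[1L]),
         call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  ids <- names(recs)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id '%s' in %s", ids[duplicated(ids)][1L], path),
         call. = FALSE)
  }
  if (any(!nzchar(ids))) stop(sprintf("parse error in %s: empty record id", path), call. = FALSE)
  seqs <- vapply(seq_along(recs),
                 function(i) canonicalise_sequence(as.character(recs[[i]]), ids[i]),
                 character(1))
  if (any(!nzchar(seqs))) {
    stop(sprintf("parse error in %s: record '%s' has an empty sequence",
                 path, ids[which(!nzchar(seqs))[1L]]), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param x A named character vector of sequences or a [cr_alignment].
#' @param path Output file path.
#' @param line_width Characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, line_width = 70L) {
  if (inherits(x, "cr_alignment")) x <- alignment_sequences(x)
  stopifnot(is.character(x), !is.null(names(x)))
  seqinr::write.fasta(as.list(x), names = names(x), file.out = path,
                      nbchar = line_width)
  invisible(path)
}

#' Construct an alignment from equal-length sequences
#'
#' The alignment is stored as a character matrix over `{A,C,G,T,-,N}` with
#' one row per record (row names are record ids) and one column per
#' alignment position.  Coordinates throughout the package are 1-based and
#' ranges are inclusive.
#'
#' @param seqs Named character vector of canonical sequences, all the same
#'   length (use [read_fasta()] to obtain canonical sequences).
#' @return An object of class `cr_alignment`.
#' @export
cr_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence not allowed", call. = FALSE)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("sequences are not aligned: lengths %s", paste(unique(lens), collapse = ", ")),
         call. = FALSE)
  }
  seqs <- vapply(seq_along(seqs), function(i) canonicalise_sequence(seqs[i], ids[i]),
                 character(1))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  structure(m, class = c("cr_alignment", class(m)))
}

#' @export
print.cr_alignment <- function(x, ...) {
  cat(sprintf("<cr_alignment> %d records x %d columns\n", nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 6L)
  for (id in show) {
    s <- paste(x[id, seq_len(min(ncol(x), 60L))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (ncol(x) > 60L) "..." else ""))
  }
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Extract sequences from an alignment
#'
#' @param aln A [cr_alignment].
#' @return Named character vector of sequences.
#' @export
alignment_sequences <- function(aln) {
  stopifnot(inherits(aln, "cr_alignment"))
  stats::setNames(apply(aln, 1L, paste, collapse = ""), rownames(aln))
}

#' Select alignment columns
#'
#' @param aln A [cr_alignment].
#' @param columns Integer vector of column indices (order preserved).
#' @return A [cr_alignment] restricted to `columns`.
#' @keywords internal
subset_columns <- function(aln, columns) {
  stopifnot(inherits(aln, "cr_alignment"))
  if (length(columns) == 0L) stop("column selection is empty", call. = FALSE)
  if (any(columns < 1L | columns > ncol(aln))) {
    stop("column selection out of bounds", call. = FALSE)
  }
  m <- aln[, columns, drop = FALSE]
  structure(m, class = c("cr_alignment", class(unclass(m))))
}

#' Select alignment records by id
#'
#' @param aln A [cr_alignment].
#' @param ids Record ids to keep (order preserved as given).
#' @return A [cr_alignment] restricted to `ids`.
#' @export
subset_records <- function(aln, ids) {
  stopifnot(inherits(aln, "cr_alignment"))
  missing_ids <- setdiff(ids, rownames(aln))
  if (length(missing_ids)) {
    stop(sprintf("record(s) not in alignment: %s", paste(missing_ids, collapse = ", ")),
         call. = FALSE)
  }
  m <- aln[ids, , drop = FALSE]
  structure(m, class = c("cr_alignment", class(unclass(m))))
}

#' Remove gap characters from a sequence
#'
#' @param x Sequence string.
#' @return `x` with all `-` removed.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

# ---------------------------------------------------------------------------
# Coordinate maps

#' Map alignment columns onto reference positions
#'
#' Builds a monotone map from 1-based alignment columns to 1-based positions
#' on a chosen reference row: a non-gap reference column `c` maps to the
#' count of non-gap reference characters in columns `1..c`, offset so that
#' the first reference base receives position `ref_start` (e.g. 15484 for a
#' control region embedded in a complete mitochondrial genome).  Gap columns
#' of the reference are unmapped.
#'
#' @param aln A [cr_alignment].
#' @param reference_id Row id of the reference sequence.
#' @param ref_start Reference position assigned to the first non-gap
#'   reference base (default 1).
#' @return An object of class `cr_coordmap` with fields `reference_id`,
#'   `columns` (mapped alignment columns) and `refpos` (their reference
#'   positions, strictly increasing).
#' @export
build_coordinate_map <- function(aln, reference_id, ref_start = 1L) {
  stopifnot(inherits(aln, "cr_alignment"))
  if (!reference_id %in% rownames(aln)) {
    stop(sprintf("reference id '%s' not present in alignment", reference_id), call. = FALSE)
  }
  refrow <- aln[reference_id, ]
  cols <- which(refrow != "-")
  if (length(cols) == 0L) {
    warning(sprintf("reference row '%s' is all gaps; coordinate map is empty", reference_id))
  }
  structure(list(reference_id = reference_id,
                 ref_start = as.integer(ref_start),
                 columns = as.integer(cols),
                 refpos = if (length(cols)) as.integer(ref_start + seq_along(cols) - 1L)
                          else integer(0)),
            class = "cr_coordmap")
}

#' Convert alignment columns to reference positions
#'
#' @param cmap A [build_coordinate_map()] result.
#' @param columns Alignment columns.
#' @return Reference positions; `NA` for unmapped (reference-gap) columns.
#' @export
column_to_refpos <- function(cmap, columns) {
  stopifnot(inherits(cmap, "cr_coordmap"))
  cmap$refpos[match(columns, cmap$columns)]
}

#' Convert reference positions to alignment columns
#'
#' @param cmap A [build_coordinate_map()] result.
#' @param positions Reference positions.
#' @return Alignment columns; `NA` for positions outside the mapped image.
#' @export
refpos_to_column <- function(cmap, positions) {
  stopifnot(inherits(cmap, "cr_coordmap"))
  cmap$columns[match(positions, cmap$refpos)]
}

# ---------------------------------------------------------------------------
# Haplotype collapsing

#' Collapse aligned sequences into haplotypes
#'
#' Two records share a haplotype iff their sequences are identical over the
#' analysed columns.  `N` is missing data and never creates a difference; a
#' record compatible with an existing haplotype joins the first such
#' haplotype in first-occurrence order, so numbering is deterministic.  By
#' default a gap is an ordinary fifth state (an indel difference separates
#' haplotypes); set `gap_as_state = FALSE` to treat gaps as missing.
#'
#' @param aln A [cr_alignment] (at least one record).
#' @param site_mask Optional integer vector of columns on which identity is
#'   assessed; default all columns.  An explicitly empty mask is an error.
#' @param gap_as_state Logical; compare `-` as a fifth state (default TRUE).
#' @return An object of class `cr_haplotypes`: list with `n_haplotypes`,
#'   `assignment` (named integer vector id -> haplotype index) and
#'   `haplotypes` (list of `members` and representative `sequence`).
#' @export
collapse_haplotypes <- function(aln, site_mask = NULL, gap_as_state = TRUE) {
  stopifnot(inherits(aln, "cr_alignment"))
  if (!is.null(site_mask)) {
    if (length(site_mask) == 0L) stop("site_mask must be non-empty", call. = FALSE)
    if (any(site_mask < 1L | site_mask > ncol(aln))) {
      stop("site_mask out of alignment bounds", call. = FALSE)
    }
    cols <- sort(unique(as.integer(site_mask)))
  } else {
    cols <- seq_len(ncol(aln))
  }
  m <- aln[, cols, drop = FALSE]
  missing_states <- if (gap_as_state) "N" else c("N", "-")
  n <- nrow(m)
  reps <- list()          # representative character vectors
  members <- list()
  assignment <- integer(n)
  for (i in seq_len(n)) {
    xi <- m[i, ]
    found <- 0L
    for (j in seq_along(reps)) {
      rj <- reps[[j]]
      informative <- !(xi %in% missing_states) & !(rj %in% missing_states)
      if (!any(xi[informative] != rj[informative])) { found <- j; break }
    }
    if (found == 0L) {
      reps[[length(reps) + 1L]] <- xi
      members[[length(members) + 1L]] <- rownames(m)[i]
      assignment[i] <- length(reps)
    } else {
      members[[found]] <- c(members[[found]], rownames(m)[i])
      assignment[i] <- found
    }
  }
  names(assignment) <- rownames(m)
  haps <- lapply(seq_along(reps), function(j) {
    list(index = j, members = members[[j]],
         sequence = paste(reps[[j]], collapse = ""))
  })
  structure(list(n_haplotypes = length(reps),
                 assignment = assignment,
                 haplotypes = haps,
                 columns = cols,
                 gap_as_state = gap_as_state),
            class = "cr_haplotypes")
}

#' @export
print.cr_haplotypes <- function(x, ...) {
  cat(sprintf("<cr_haplotypes> %d haplotypes among %d records (%d analysed columns)\n",
              x$n_haplotypes, length(x$assignment), length(x$columns)))
  invisible(x)
}

#' Tabulate a haplotype set
#'
#' @param hs A [collapse_haplotypes()] result.
#' @param path Optional output path; if given the table is written as TSV.
#' @return Data frame with columns `haplotype_index`, `n_members`,
#'   `member_ids` (comma-separated) and `sequence_md5`.
#' @export
haplotype_report <- function(hs, path = NULL) {
  stopifnot(inherits(hs, "cr_haplotypes"))
  md5_of <- function(s) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeLines(s, tf, sep = "")
    unname(tools::md5sum(tf))
  }
  df <- data.frame(
    haplotype_index = vapply(hs$haplotypes, `[[`, integer(1), "index"),
    n_members = vapply(hs$haplotypes, function(h) length(h$members), integer(1)),
    member_ids = vapply(hs$haplotypes, function(h) paste(h$members, collapse = ","),
                        character(1)),
    sequence_md5 = vapply(hs$haplotypes, function(h) md5_of(h$sequence), character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
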