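# Distance matrices, neighbor-joining trees, clade-concordance testing and
# NEXUS export.  Distance-based trees stand in as the in-package estimator;
# NEXUS export allows the same alignments to be analysed with external
# Bayesian software.

#' Pairwise distance matrix
#'
#' Computes p-distances (differences per comparable site) or
#' Kimura two-parameter distances from transition and transversion
#' proportions, `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.  For K2P only
#' unambiguous bases are comparable regardless of policy (a gap has no
#' transition/transversion identity).  Saturated pairs, where a logarithm
#' argument is non-positive, are assigned the maximum finite distance
#' observed and listed in the `saturated` attribute.
#'
#' @param aln A [cr_alignment] with at least 3 records.
#' @param model `"p"` or `"k2p"`.
#' @param policy A [gap_policy()]; under `include_gaps` a base-gap
#'   mismatch counts as a p-distance difference.
#' @return Symmetric numeric matrix with zero diagonal and record ids as
#'   dimnames; attributes `model`, `policy`, `saturated`.
#' @export
distance_matrix <- function(aln, model = c("p", "k2p"),
                            policy = "pairwise_deletion") {
  stopifnot(inherits(aln, "cr_alignment"))
  model <- match.arg(model)
  policy <- gap_policy(policy)
  if (nrow(aln) < 3L) stop("at least 3 records are required", call. = FALSE)
  n <- nrow(aln)
  ids <- rownames(aln)
  cols <- if (policy == "complete_deletion") analyzed_sites(aln, policy) else seq_len(ncol(aln))
  m <- aln[, cols, drop = FALSE]
  counted <- counted_states_set(policy)
  purine <- c("A", "G")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  saturated <- character(0)
  for (i in seq_len(n - 1L)) {
    xi <- m[i, ]
    for (j in (i + 1L):n) {
      xj <- m[j, ]
      if (model == "p") {
        ok <- xi %in% counted & xj %in% counted
        if (!any(ok)) {
          stop(sprintf("no comparable sites for pair (%s, %s)", ids[i], ids[j]),
               call. = FALSE)
        }
        dij <- sum(xi[ok] != xj[ok]) / sum(ok)
      } else {
        ok <- xi %in% .DNA_STATES & xj %in% .DNA_STATES
        if (!any(ok)) {
          stop(sprintf("no comparable sites for pair (%s, %s)", ids[i], ids[j]),
               call. = FALSE)
        }
        a <- xi[ok]; b <- xj[ok]
        diff <- a != b
        ts <- diff & ((a %in% purine) == (b %in% purine))
        P <- sum(ts) / sum(ok)
        Q <- sum(diff & !ts) / sum(ok)
        arg1 <- 1 - 2 * P - Q
        arg2 <- 1 - 2 * Q
        if (arg1 <= 0 || arg2 <= 0) {
          dij <- NA_real_
          saturated <- c(saturated, paste(ids[i], ids[j], sep = "|"))
        } else {
          dij <- -0.5 * log(arg1) - 0.25 * log(arg2)
        }
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (anyNA(d)) {
    finite_max <- max(d[is.finite(d)], 0)
    d[is.na(d)] <- finite_max
  }
  structure(d, model = model, policy = policy, saturated = saturated)
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining with deterministic behaviour: taxa are sorted
#' lexicographically before agglomeration so identical matrices always give
#' the same tree, and negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch so path lengths are preserved.
#'
#' @param dm A symmetric distance matrix with dimnames (e.g. from
#'   [distance_matrix()]), at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("at least 3 taxa are required", call. = FALSE)
  ids <- sort(rownames(dm))
  dm <- dm[ids, ids]
  tree <- ape::nj(stats::as.dist(dm))
  clamp_negative_edges(tree)
}

# Clamp negative edge lengths to 0, transferring the deficit to the sibling
# edge (the other edge sharing the parent node) so root-to-tip path sums
# change as little as possible.
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[which.min(tree$edge.length[neg])]
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sib <- which(tree$edge[, 1L] == parent & seq_len(nrow(tree$edge)) != e)
    if (length(sib)) {
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + deficit
    }
  }
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return The (even, non-negative) count of bipartitions present in one
#'   tree but not the other.
#' @export
rf_distance <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
}

#' Group labelling for concordance tests
#'
#' @param ids Sequence ids.
#' @param groups Group label per id (`NA` for unlabelled query sequences).
#' @param outgroup Character vector of outgroup ids.
#' @return An object of class `cr_labels`.
#' @export
group_labels <- function(ids, groups, outgroup = character(0)) {
  stopifnot(length(ids) == length(groups))
  if (anyDuplicated(ids)) stop("duplicate ids in labelling", call. = FALSE)
  labelled <- groups[!is.na(groups) & !(ids %in% outgroup)]
  if (length(unique(labelled)) < 2L) {
    stop("at least 2 labelled groups are required for concordance tests", call. = FALSE)
  }
  structure(list(ids = ids, groups = stats::setNames(groups, ids),
                 outgroup = outgroup),
            class = "cr_labels")
}

# Assign each query leaf to a labelled group on a rooted tree: ascend from
# the query tip to the smallest enclosing clade that contains at least one
# labelled leaf; if every labelled leaf in that clade carries one group
# label the query is assigned to it, otherwise (mixed labels, i.e. the
# query is placed ambiguously between groups) it is "unassigned".
assign_queries <- function(tree, labels, queries) {
  grp <- labels$groups
  labelled <- names(grp)[!is.na(grp) & !(names(grp) %in% labels$outgroup)]
  labelled <- intersect(labelled, tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  vapply(queries, function(q) {
    node <- match(q, tree$tip.label)
    repeat {
      if (node == root) break
      node <- parent_of[node]
      desc <- tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1L]]]
      inside <- intersect(desc, labelled)
      if (length(inside)) {
        gs <- unique(grp[inside])
        return(if (length(gs) == 1L) unname(gs) else "unassigned")
      }
    }
    "unassigned"
  }, character(1))
}

#' Clade concordance across trees
#'
#' Roots every tree on the outgroup, tests each labelled group for
#' monophyly, assigns every unlabelled (query) leaf to the group of the
#' smallest group clade containing it (ambiguous placements are reported as
#' `"unassigned"`, never silently attributed), and measures pairwise
#' Robinson-Foulds distances and same-clade assignment agreement, i.e. the
#' fraction of queries placed identically by two trees.
#'
#' @param trees Named list of `phylo` trees; leaf sets are restricted to
#'   their common leaves, which must include the outgroup and at least 4
#'   tips.
#' @param labels A [group_labels()] object.
#' @return An object of class `cr_concordance`: list with `monophyly`
#'   (group x tree logical matrix), `rf` (tree x tree matrix),
#'   `assignments` (query x tree character matrix) and `agreement`
#'   (tree x tree matrix of assignment agreement in [0, 1]).
#' @export
concordance <- function(trees, labels) {
  stopifnot(is.list(trees), length(trees) >= 2L, inherits(labels, "cr_labels"))
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  common <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(common) < 4L) stop("trees share fewer than 4 leaves", call. = FALSE)
  og <- intersect(labels$outgroup, common)
  if (length(og) == 0L) stop("outgroup absent from the shared leaf set", call. = FALSE)
  trees <- lapply(trees, function(t) {
    t <- ape::keep.tip(t, common)
    ape::root(t, outgroup = og, resolve.root = TRUE)
  })
  grp <- labels$groups
  group_names <- unique(grp[!is.na(grp) & !(names(grp) %in% labels$outgroup)])
  group_names <- group_names[!is.na(group_names)]
  # monophyly is assessed among the labelled leaves themselves (plus the
  # outgroup): unlabelled queries nested inside a group's clade must not
  # break it
  labelled_ids <- names(grp)[!is.na(grp)]
  mono <- sapply(trees, function(t) {
    tl <- ape::keep.tip(t, intersect(t$tip.label, c(labelled_ids, og)))
    vapply(group_names, function(g) {
      tips <- intersect(names(grp)[!is.na(grp) & grp == g], tl$tip.label)
      if (length(tips) < 2L) return(TRUE)
      ape::is.monophyletic(tl, tips)
    }, logical(1))
  })
  mono <- matrix(mono, nrow = length(group_names),
                 dimnames = list(group_names, names(trees)))
  queries <- setdiff(common, c(og, names(grp)[!is.na(grp)]))
  assign <- if (length(queries)) {
    do.call(cbind, lapply(trees, assign_queries, labels = labels, queries = queries))
  } else {
    matrix(character(0), nrow = 0L, ncol = length(trees))
  }
  dimnames(assign) <- list(queries, names(trees))
  nt <- length(trees)
  rf <- matrix(0, nt, nt, dimnames = list(names(trees), names(trees)))
  agree <- matrix(1, nt, nt, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]])
      agree[i, j] <- agree[j, i] <-
        if (nrow(assign)) mean(assign[, i] == assign[, j]) else 1
    }
  }
  structure(list(monophyly = mono, rf = rf, assignments = assign,
                 agreement = agree, trees = trees, outgroup = og),
            class = "cr_concordance")
}

#' @export
print.cr_concordance <- function(x, ...) {
  cat(sprintf("<cr_concordance> %d trees, %d groups, %d query leaves\n",
              length(x$trees), nrow(x$monophyly), nrow(x$assignments)))
  cat("monophyly:\n"); print(x$monophyly)
  cat("assignment agreement:\n"); print(round(x$agreement, 3L))
  invisible(x)
}

#' Export an alignment as sequential NEXUS
#'
#' Writes a sequential DATA block with `datatype=DNA`, `gap='-'` and
#' `missing='N'`, readable by common phylogenetics software.
#'
#' @param aln A [cr_alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_nexus <- function(aln, path) {
  stopifnot(inherits(aln, "cr_alignment"))
  x <- lapply(seq_len(nrow(aln)), function(i) unname(aln[i, ]))
  names(x) <- rownames(aln)
  ape::write.nexus.data(x, file = path, format = "dna", interleaved = FALSE,
                        gap = "-", missing = "N")
  invisible(path)
}

#' Read a NEXUS data block back as an alignment
#'
#' @param path A NEXUS file with a DNA data block.
#' @return A [cr_alignment].
#' @export
read_nexus_alignment <- function(path) {
  x <- ape::read.nexus.data(path)
  seqs <- vapply(x, function(ch) paste(ch, collapse = ""), character(1))
  cr_alignment(seqs)
}
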