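test_that("p and K2P distances follow their closed forms", {
  # identical pair -> 0 under both models
  aln0 <- cr_alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_true(all(distance_matrix(aln0, "p") == 0))
  expect_true(all(distance_matrix(aln0, "k2p") == 0))

  # one transition among 100 comparable sites
  base <- strrep("A", 99)
  aln <- cr_alignment(c(x = paste0(base, "A"), y = paste0(base, "G"),
                        z = paste0(base, "A")))
  dp <- distance_matrix(aln, "p")
  expect_equal(dp["x", "y"], 0.01)
  dk <- distance_matrix(aln, "k2p")
  expect_equal(dk["x", "y"], -0.5 * log(1 - 2 * 0.01) - 0.25 * log(1))

  expect_error(distance_matrix(cr_alignment(c(a = "AC", b = "AC"))), "at least 3")
})

test_that("distance matrices are symmetric and permutation-equivariant", {
  set.seed(3)
  seqs <- random_toy_alignment(6, 60)
  dm <- distance_matrix(cr_alignment(seqs), "p")
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  perm <- sample(names(seqs))
  dm2 <- distance_matrix(cr_alignment(seqs[perm]), "p")
  expect_equal(dm2[perm, perm], dm[perm, perm])
})

test_that("K2P agrees with an established implementation on gap-free data", {
  set.seed(5)
  seqs <- random_toy_alignment(6, 200, p_mut = 0.1, p_gap = 0, p_n = 0)
  dm <- distance_matrix(cr_alignment(seqs), "k2p")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(unname(dm[names(seqs), names(seqs)]),
               unname(ref[names(seqs), names(seqs)]), tolerance = 1e-10)
})

test_that("saturated K2P pairs are flagged and given the maximum finite distance", {
  aln <- cr_alignment(c(a = strrep("A", 40),
                        b = strrep("G", 40),
                        c = paste0(strrep("A", 36), "GGGG")))
  dm <- distance_matrix(aln, "k2p")
  expect_false(anyNA(dm))
  expect_gte(length(attr(dm, "saturated")), 1L)
  expect_equal(max(dm), dm["a", "b"])
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(7)
  for (rep in 1:10) {
    tree <- ape::rtree(8, rooted = FALSE, br = function(n) runif(n, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(tree)
    est <- nj_tree(dm)
    expect_equal(rf_distance(est, tree), 0)
    expect_true(all(est$edge.length >= 0))
    # branch lengths of an additive matrix are recovered too
    expect_equal(sort(est$edge.length), sort(tree$edge.length), tolerance = 1e-8)
  }
})

test_that("three taxa give the unique unrooted topology", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(rf_distance(tr, tr), 0)
})

test_that("RF distance is zero on self, symmetric, even, and 2 after one NNI", {
  set.seed(11)
  t1 <- ape::rtree(10, rooted = FALSE)
  t2 <- ape::rtree(10, rooted = FALSE)
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
  expect_equal(rf_distance(t1, t2) %% 2, 0)

  # one NNI around an internal edge changes exactly one bipartition
  t3 <- ape::read.tree(text = "((a,b),c,(d,e));")
  t4 <- ape::read.tree(text = "((a,c),b,(d,e));")
  expect_equal(rf_distance(t3, t4), 2)
})

test_that("concordance on identical trees is perfect", {
  gen <- generate_alignment(syn_config(), seed = 13)
  truth <- gen$truth$labels
  labelled <- unlist(lapply(split(truth$id[!truth$is_outgroup],
                                  truth$clade[!truth$is_outgroup]), head, 4))
  labels <- group_labels(truth$id,
                         ifelse(truth$id %in% labelled, truth$clade, NA),
                         outgroup = truth$id[truth$is_outgroup])
  tr <- nj_tree(distance_matrix(gen$alignment, "p"))
  rep2 <- concordance(list(one = tr, two = tr), labels)
  expect_equal(rep2$rf["one", "two"], 0)
  expect_equal(rep2$agreement["one", "two"], 1)
})

test_that("segment and remainder trees assign queries to their generating clades", {
  ce <- concordance_experiment(seed = 3)
  expect_equal(unname(ce$accuracy["segment"]), 1)
  expect_equal(unname(ce$accuracy["remainder"]), 1)
  expect_equal(ce$agreement_segment_remainder, 1)
  expect_true(all(ce$report$monophyly))
})

test_that("concordance degrades as between-clade divergence shrinks", {
  hi <- concordance_experiment(seed = 5, clade_divergence = 0.01)
  lo <- concordance_experiment(seed = 5, clade_divergence = 0.0005)
  expect_lt(lo$agreement_segment_remainder, hi$agreement_segment_remainder)
})

test_that("NEXUS export round-trips sequences, gaps and Ns", {
  gen <- generate_alignment(syn_config(), seed = 17)
  aln <- gen$alignment
  # plant an N to exercise the missing symbol
  seqs <- alignment_sequences(aln)
  substr(seqs[1], 5, 5) <- "N"
  aln <- cr_alignment(seqs)
  path <- tempfile(fileext = ".nex")
  export_nexus(aln, path)
  txt <- readLines(path)
  expect_true(any(grepl("ntax=38", txt, ignore.case = TRUE)))
  expect_true(any(grepl("nchar=1020", txt, ignore.case = TRUE)))
  back <- read_nexus_alignment(path)
  expect_equal(alignment_sequences(back), alignment_sequences(aln))
})

test_that("a 3-record toy NEXUS block declares its dimensions", {
  aln <- cr_alignment(c(a = "ACG-TN", b = "ACGTTA", c = "ACGTTC"))
  path <- tempfile(fileext = ".nex")
  export_nexus(aln, path)
  txt <- paste(readLines(path), collapse = "\n")
  expect_match(txt, "ntax=3", ignore.case = TRUE)
  expect_match(txt, "nchar=6", ignore.case = TRUE)
  back <- read_nexus_alignment(path)
  expect_equal(alignment_sequences(back), alignment_sequences(aln))
})
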