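test_that("window geometry matches the anchored no-trailing-window convention", {
  set.seed(1)
  seqs <- random_toy_alignment(4, 1022, p_gap = 0, p_n = 0)
  aln <- cr_alignment(seqs)
  prof <- window_profile(aln, 100, 25)
  expect_equal(nrow(prof), floor((1022 - 100) / 25) + 1)  # 37 windows
  expect_equal(prof$start[1], 1)
  expect_true(all(diff(prof$start) == 25))
  expect_true(all(prof$pi >= 0 & prof$pi <= 1))

  expect_error(window_profile(aln, 2000, 25), "window length")
  expect_error(window_profile(aln, 100, 0), "step")
})

test_that("monomorphic alignments profile flat at zero and delimit one conserved region", {
  seqs <- stats::setNames(rep(paste(rep("ACGT", 60), collapse = ""), 4),
                          paste0("s", 1:4))
  aln <- cr_alignment(seqs)
  prof <- window_profile(aln, 100, 25)
  expect_true(all(prof$pi == 0))
  reg <- delimit_regions(prof, aln)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$label, "conserved")
  expect_equal(reg$start, 1L)
  expect_false(any(reg$hvri))
})

test_that("variation placement drives the profile and per-window counts match an oracle", {
  set.seed(5)
  base <- paste(rep("A", 120), collapse = "")
  # all variation confined to columns 1-20
  mk <- function(variant_chars) {
    s <- strsplit(base, "")[[1]]
    s[1:20] <- variant_chars
    paste(s, collapse = "")
  }
  seqs <- c(a = mk(rep("A", 20)), b = mk(rep("C", 20)),
            c = mk(rep("G", 20)), d = mk(rep("T", 20)))
  aln <- cr_alignment(seqs)
  prof <- window_profile(aln, 60, 15)
  expect_equal(prof$start[which.max(prof$pi)], 1)
  expect_true(all(prof$pi[prof$start > 20] == 0))

  # per-window S against direct counting on the sub-alignment
  for (i in seq_len(nrow(prof))) {
    cols <- prof$start[i]:prof$end[i]
    sub <- cr_alignment(vapply(seqs, function(s) {
      paste(strsplit(s, "")[[1]][cols], collapse = "")
    }, character(1)))
    expect_equal(prof$S[i], segregating_sites(sub)$S)
  }
})

test_that("conservation threshold is the uniform-scatter expectation", {
  set.seed(2)
  seqs <- random_toy_alignment(5, 200, p_gap = 0, p_n = 0)
  aln <- cr_alignment(seqs)
  seg <- segregating_sites(aln)
  expect_equal(conservation_threshold(aln, 50),
               seg$S * 50 / length(analyzed_sites(aln, "complete_deletion")))

  mono <- cr_alignment(stats::setNames(rep(strrep("ACGT", 50), 3), paste0("m", 1:3)))
  expect_equal(conservation_threshold(mono, 50), 0)
})

test_that("window profile is invariant to record order", {
  set.seed(9)
  gen <- generate_alignment(syn_config(), seed = 31)
  seqs <- alignment_sequences(gen$alignment)
  prof1 <- window_profile(cr_alignment(seqs))
  prof2 <- window_profile(cr_alignment(seqs[sample(length(seqs))]))
  expect_equal(prof1$pi, prof2$pi)
  expect_equal(prof1$S, prof2$S)
})

test_that("non-overlapping windows partition the pairwise difference total", {
  set.seed(13)
  seqs <- random_toy_alignment(6, 120, p_gap = 0.04)
  aln <- cr_alignment(seqs)
  prof <- window_profile(aln, 30, 30)  # step == window_length, 120 = 4 x 30
  pd <- ctrlregion:::pair_difference_matrix(aln, "complete_deletion")
  total <- sum(pd$diffs[upper.tri(pd$diffs)])
  expect_equal(sum(prof$n_pair_diffs), total)
})

test_that("delimited regions label every covered column exactly once", {
  gen <- generate_alignment(syn_config(), seed = 17)
  prof <- window_profile(gen$alignment)
  reg <- delimit_regions(prof, gen$alignment)
  covered <- unlist(lapply(seq_len(nrow(reg)), function(i) reg$start[i]:reg$end[i]))
  expect_false(any(duplicated(covered)))
  expect_equal(sort(covered), min(prof$start):max(prof$end))
  expect_true(reg$hvri[which(reg$label == "hypervariable")[1]])
  expect_error(delimit_regions(prof[0, ], gen$alignment), "empty")
})

test_that("the planted left-domain block is recovered within one step", {
  gen <- generate_alignment(syn_config(), seed = 101)
  prof <- window_profile(gen$alignment)
  reg <- delimit_regions(prof, gen$alignment)
  hv <- reg[reg$hvri, ]
  expect_equal(nrow(hv), 1L)
  expect_lte(abs(hv$start - 1), 25)
  expect_lte(abs(hv$end - 380), 25)
})

test_that("refining the step moves boundaries by at most the old step", {
  gen <- generate_alignment(syn_config(), seed = 55)
  aln <- gen$alignment
  reg25 <- delimit_regions(window_profile(aln, 100, 25), aln)
  reg5 <- delimit_regions(window_profile(aln, 100, 5), aln)
  b25 <- reg25$end[reg25$hvri]
  b5 <- reg5$end[reg5$hvri]
  expect_lte(abs(b25 - b5), 25)
})

test_that("secondary hypervariable blocks at distinct positions are told apart", {
  cfg_a <- syn_config(blocks = list(c(1, 380, 8), c(550, 650, 8)))
  cfg_b <- syn_config(blocks = list(c(1, 380, 8), c(750, 850, 8)))
  hv_of <- function(cfg, seed) {
    gen <- generate_alignment(cfg, seed = seed)
    reg <- delimit_regions(window_profile(gen$alignment), gen$alignment)
    reg[reg$label == "hypervariable" & !reg$hvri, c("start", "end")]
  }
  a <- hv_of(cfg_a, 71)
  b <- hv_of(cfg_b, 71)
  expect_gte(nrow(a), 1)
  expect_gte(nrow(b), 1)
  # the secondary intervals do not overlap between the two panels
  expect_true(max(a$end) < min(b$start))
})

test_that("regions translate to reference coordinates through the map", {
  gen <- generate_alignment(syn_config(), seed = 3)
  aln <- gen$alignment
  ref_id <- rownames(aln)[1]
  cmap <- build_coordinate_map(aln, ref_id, ref_start = 15484L)
  reg <- delimit_regions(window_profile(aln), aln)
  ref_reg <- regions_to_reference(reg, cmap)
  expect_equal(nrow(ref_reg), nrow(reg))
  expect_true(all(ref_reg$ref_start >= 15484L))
  expect_true(all(ref_reg$ref_end >= ref_reg$ref_start))
})
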