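test_that("resolution report counts merged haplotype groups", {
  # three full haplotypes differing only outside columns 1-4
  aln <- cr_alignment(c(a = "ACGTAAAA", b = "ACGTAAAT", c = "ACGTAATT"))
  sp <- segment_spec("left", cbind(1L, 4L))
  res <- resolution_report(aln, sp)
  expect_equal(res$h_full, 3L)
  expect_equal(res$h_segment, 1L)
  expect_length(res$collapsed_groups, 1L)
  expect_setequal(res$collapsed_groups[[1]], c("a", "b", "c"))

  full <- resolution_report(aln, segment_spec("all", cbind(1L, 8L)))
  expect_equal(full$discrimination_percent, 100)
  expect_length(full$collapsed_groups, 0L)
})

test_that("discrimination is monotone over nested segments", {
  gen <- generate_alignment(syn_config(), seed = 19)
  ends <- c(150L, 300L, 450L, 700L, 1020L)
  h <- vapply(ends, function(e) {
    resolution_report(gen$alignment, segment_spec("n", cbind(1L, e)))$h_segment
  }, integer(1))
  expect_true(all(diff(h) >= 0))
})

test_that("between-clade signal outside a segment is invisible to it", {
  # clade differences confined to columns > 400: left-domain specs cannot
  # discriminate between clades, the full span can
  # columns 1-400 are silenced with a vanishing rate multiplier
  cfg <- syn_config(n_cols = 1020,
                    clades = c(A = 5L, B = 5L),
                    clade_divergence = 0.05,
                    tip_divergence = 0,
                    blocks = list(c(1, 400, 1e-9)),
                    indels = list(),
                    n_outgroup = 0)
  gen <- generate_alignment(cfg, seed = 23)
  left <- resolution_report(gen$alignment, segment_spec("left", cbind(1L, 400L)))
  full <- resolution_report(gen$alignment, segment_spec("all", cbind(1L, 1020L)))
  expect_lt(left$discrimination_percent, 100)
  expect_equal(full$discrimination_percent, 100)
})

test_that("the deletion locus is recovered from an aligned reference pair", {
  gen <- generate_alignment(syn_config(), seed = 29)
  seqs <- alignment_sequences(gen$alignment)
  carriers <- gen$truth$indel_carriers[[1]]
  non_carrier <- setdiff(gen$truth$labels$id[!gen$truth$labels$is_outgroup], carriers)[1]
  locus <- find_deletion_locus(seqs[[non_carrier]], seqs[[carriers[1]]])
  expect_equal(locus$length, 15L)
  expect_equal(locus$start, 986L)  # no gaps left of the locus in this design
  expect_equal(nchar(locus$left_flank), 12L)
  expect_equal(nchar(locus$right_flank), 12L)

  expect_error(find_deletion_locus(seqs[[non_carrier]], seqs[[non_carrier]]),
               "no deletion")
})

test_that("species classification recovers every synthetic carrier and non-carrier", {
  res <- species_classification_experiment(n_panels = 6, seed = 47)
  expect_gte(res$n_classified, 200)
  expect_equal(res$accuracy, 1)
})

test_that("classification falls back on length and flags boundary cases", {
  expect_equal(classify_species_by_deletion(strrep("ACGT", 250)), "bornean-like")   # 1000
  expect_equal(classify_species_by_deletion(strrep("ACGT", 254)), "sumatran-like")  # 1016
  expect_error(classify_species_by_deletion(strrep("ACGT", 100)), "input error")

  # locus present but deletion-sized length: indeterminate with a warning
  gen <- generate_alignment(syn_config(), seed = 53)
  seqs <- alignment_sequences(gen$alignment)
  carriers <- gen$truth$indel_carriers[[1]]
  non_carrier <- setdiff(gen$truth$labels$id[!gen$truth$labels$is_outgroup], carriers)[1]
  locus <- find_deletion_locus(seqs[[non_carrier]], seqs[[carriers[1]]])
  s <- degap(seqs[[non_carrier]])
  shrunk <- paste0(substr(s, 1, 400), substr(s, 416, nchar(s)))  # drop 15 bp elsewhere
  expect_warning(lab <- classify_species_by_deletion(shrunk, locus = locus),
                 "indeterminate")
  expect_equal(lab, "indeterminate")
})

test_that("in-silico PCR finds the unique product and is a fixpoint", {
  set.seed(61)
  primers <- builtin_primers()
  pair <- primer_pair(primers$CYTBMIDF, primers$`133R`,
                      names = c("CYTBMIDF", "133R"))
  insert <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = "")
  lead <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  tail_ <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  template <- paste0(lead, pair$forward, insert, reverse_complement(pair$reverse), tail_)

  amp <- in_silico_pcr(template, pair)
  # oracle by exact string arithmetic
  expect_equal(amp$forward_start, nchar(lead) + 1L)
  expect_equal(amp$product_length, nchar(pair$forward) + 1500L + nchar(pair$reverse))
  expect_equal(amp$product,
               paste0(pair$forward, insert, reverse_complement(pair$reverse)))

  # re-amplification of the product returns the identical product
  amp2 <- in_silico_pcr(amp$product, pair)
  expect_equal(amp2$product, amp$product)
  expect_equal(amp2$forward_start, 1L)
})

test_that("in-silico PCR fails informatively on bad templates", {
  set.seed(67)
  primers <- builtin_primers()
  pair <- primer_pair(primers$CRMIDF, primers$CRMIDR)
  random <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
  expect_error(in_silico_pcr(random, pair), "no-hit")

  # two identical forward sites -> ambiguous
  tpl <- paste0(pair$forward, strrep("A", 300), pair$forward, strrep("A", 300),
                reverse_complement(pair$reverse))
  expect_error(in_silico_pcr(tpl, pair), "ambiguous")

  # product shorter than plausible
  short <- paste0(pair$forward, "ACGTACGT", reverse_complement(pair$reverse))
  expect_error(in_silico_pcr(short, pair), "implausible product length")
})

test_that("primer mismatch model keeps the 3' terminus exact", {
  set.seed(71)
  primers <- builtin_primers()
  pair <- primer_pair(primers$CYTBMIDF, primers$`133R`)
  insert <- paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE), collapse = "")
  mutate_at <- function(p, i) {
    ch <- substr(p, i, i)
    substr(p, i, i) <- setdiff(c("A", "C", "G", "T"), ch)[1]
    p
  }
  # one internal mismatch in the template's forward site: rejected at 0,
  # accepted at 1 mismatch
  fwd_site <- mutate_at(pair$forward, 5L)
  template <- paste0(fwd_site, insert, reverse_complement(pair$reverse))
  expect_error(in_silico_pcr(template, pair, max_mismatches = 0), "no-hit")
  amp <- in_silico_pcr(template, pair, max_mismatches = 1)
  expect_equal(amp$forward_mismatches, 1L)

  # mismatch in the 3'-terminal 3 bases is rejected at any setting
  fwd_3p <- mutate_at(pair$forward, nchar(pair$forward))
  template2 <- paste0(fwd_3p, insert, reverse_complement(pair$reverse))
  expect_error(in_silico_pcr(template2, pair, max_mismatches = 3), "no-hit")
})
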