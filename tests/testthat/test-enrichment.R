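test_that("padding extends and clips TE copies", {
  gm <- genome_model(tibble::tibble(chrom = "chr1", length = 1200L))
  te <- tibble::tibble(copy_id = "c1", family = "f:ERV1:LTR",
                       superfamily = "ERV1", te_class = "LTR",
                       chrom = "chr1", start = 500L, end = 700L, strand = "+")
  p <- pad_te_intervals(te, 1000, genome = gm)
  expect_equal(c(p$start, p$end), c(0L, 1200L))
  expect_equal(pad_te_intervals(te, 0)[, c("start", "end")],
               te[, c("start", "end")])
})

test_that("observed overlap counts peak-copy events and matches brute force", {
  te <- tibble::tibble(
    copy_id = c("c1", "c2"), family = "f:ERV1:LTR",
    superfamily = "ERV1", te_class = "LTR",
    chrom = "chr1", start = c(100L, 180L), end = c(200L, 260L), strand = "+"
  )
  empty <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  expect_equal(unname(observed_overlap(empty, te)), 0)
  one <- tibble::tibble(chrom = "chr1", start = 120L, end = 140L)
  expect_equal(unname(observed_overlap(one, te)), 1)
  # a peak spanning both copies contributes 2 events but 1 distinct peak
  span <- tibble::tibble(chrom = "chr1", start = 150L, end = 250L)
  expect_equal(unname(observed_overlap(span, te)), 2)
  expect_equal(unname(observed_overlap(span, te, count = "distinct_peaks")), 1)

  set.seed(61)
  peaks <- rand_intervals(300)
  gm <- simulate_genome(2, 1e5, 0, seed = 1)
  te_big <- simulate_te_annotation(gm, 5, 20, c(100L, 400L), seed = 2)
  got <- observed_overlap(peaks, te_big)
  pairs <- brute_overlap_pairs(peaks, te_big)
  want <- table(factor(te_big$family[pairs$subject_idx],
                       levels = unique(te_big$family)))
  expect_equal(unname(got), as.numeric(want))
})

test_that("shuffles preserve lengths and respect the excluded mask", {
  gm <- simulate_genome(1, 1e5, 0.2, seed = 3)
  te <- simulate_te_annotation(gm, 2, 10, c(100L, 300L), seed = 4)
  padded <- pad_te_intervals(te, 100, genome = gm)
  peaks <- simulate_peaks(gm, te, n_peaks = 50, peak_len = 200, seed = 5)$peaks
  null <- shuffle_te_null(padded, gm, peaks, n_shuffles = 50, seed = 6)
  expect_equal(dim(null), c(50, 2))
  # determinism
  expect_identical(null, shuffle_te_null(padded, gm, peaks, 50, seed = 6))
})

test_that("a fully excluded genome cannot be shuffled", {
  sizes <- tibble::tibble(chrom = "chr1", length = 1000L)
  gm <- genome_model(sizes, tibble::tibble(chrom = "chr1", start = 0L, end = 1000L))
  te <- tibble::tibble(copy_id = "c1", family = "f:ERV1:LTR",
                       superfamily = "ERV1", te_class = "LTR",
                       chrom = "chr1", start = 0L, end = 100L, strand = "+")
  peaks <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  expect_error(shuffle_te_null(te, gm, peaks, 10), "no shuffle space")
})

test_that("the shuffle null mean matches the closed-form uniform expectation", {
  gm <- simulate_genome(1, 2e5, 0, seed = 7)
  te <- simulate_te_annotation(gm, 2, 15, c(200L, 400L), seed = 8)
  padded <- pad_te_intervals(te, 500, genome = gm)
  peaks <- simulate_peaks(gm, te, n_peaks = 60, peak_len = 300, seed = 9)$peaks
  null <- shuffle_te_null(padded, gm, peaks, n_shuffles = 1000, seed = 10)
  expected <- expected_shuffle_events(padded, gm, peaks)
  for (fam in colnames(null)) {
    se <- sd(null[, fam]) / sqrt(nrow(null))
    expect_lt(abs(mean(null[, fam]) - expected[[fam]]), 3 * se + 1e-9)
  }
})

test_that("enrichment tails match exact binomial enumeration", {
  null <- rep(10, 100)  # null_mean 10
  res <- enrichment_test(30, null, n_peaks = 100)
  expect_equal(res$p_binomial, binom_upper_oracle(30, 100, 0.1),
               tolerance = 1e-12)
  expect_equal(res$direction, "enriched")

  res0 <- enrichment_test(0, null, n_peaks = 100)
  expect_equal(res0$p_binomial, binom_lower_oracle(0, 100, 0.1),
               tolerance = 1e-12)
  expect_equal(res0$direction, "depleted")

  # observed equal to the null mean is never significant
  res_eq <- enrichment_test(10, null, n_peaks = 100)
  expect_equal(res_eq$direction, "ns")
  expect_gt(res_eq$p_binomial, 0.4)

  # empty case
  res_empty <- enrichment_test(0, rep(0, 10), n_peaks = 100)
  expect_equal(res_empty$p_binomial, 1)
  expect_equal(res_empty$direction, "ns")
})

test_that("the full family test flags a planted enriched family", {
  gm <- simulate_genome(1, 1e6, 0, seed = 11)
  te <- simulate_te_annotation(gm, 4, 15, c(200L, 400L), seed = 12)
  target <- unique(te$family)[1]
  peaks <- simulate_peaks(gm, te, target, enrichment_factor = 8,
                          n_peaks = 150, peak_len = 300, pad = 1000,
                          seed = 13)$peaks
  enr <- te_family_enrichment(peaks, te, gm, pad = 1000, n_shuffles = 300,
                              seed = 14)
  tab <- tidy(enr)
  expect_equal(tab$direction[tab$family == target], "enriched")
  expect_true(all(c("p_binomial", "p_hypergeometric") %in% names(tab)))
  expect_true(all(tab$p_binomial >= 0 & tab$p_binomial <= 1))
})

test_that("crossing with DE flags only families that are both", {
  enr_tab <- tibble::tibble(
    family = c("A", "B", "C"),
    n_copies = 5, observed = c(30, 30, 5), null_mean = 10, null_sd = 3,
    p_binomial = c(1e-6, 1e-6, 0.7), p_hypergeometric = NA_real_,
    direction = c("enriched", "enriched", "ns")
  )
  crossed <- cross_with_de(enr_tab, list(up = "A", down = character()))
  expect_equal(crossed$flagged, c(TRUE, FALSE, FALSE))
  none <- cross_with_de(enr_tab, list(up = character(), down = character()))
  expect_false(any(none$flagged))
})
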