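test_that("size factors: identity, scale equivariance, oracle parity", {
  m <- tibble::tibble(feature_id = paste0("f", 1:10),
                      s1 = rpois(10, 100) + 1)
  m$s2 <- m$s1
  expect_equal(unname(size_factors(m)), c(1, 1))

  m$s2 <- 2 * m$s1
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  # independent median-of-ratios oracle on a random NB matrix
  set.seed(31)
  mat <- matrix(rnbinom(500 * 4, mu = 100, size = 10), ncol = 4,
                dimnames = list(paste0("f", 1:500), paste0("s", 1:4)))
  oracle <- apply(mat, 2, function(col) {
    keep <- rowSums(mat > 0) == ncol(mat)
    ratios <- col[keep] / exp(rowMeans(log(mat[keep, , drop = FALSE])))
    median(ratios)
  })
  expect_equal(unname(size_factors(mat)), unname(oracle), tolerance = 1e-12)
})

test_that("size factors fall back to totals when no feature is always nonzero", {
  mat <- matrix(c(5, 0, 0, 7), nrow = 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(sf <- size_factors(mat), "total-count")
  expect_equal(unname(sf[2] / sf[1]), 7 / 5, tolerance = 1e-12)
})

test_that("identical constant groups give zero fold change and ns", {
  counts <- tibble::tibble(feature_id = c("a", "b"), kind = "gene",
                           s1 = c(50, 80), s2 = c(50, 80),
                           s3 = c(50, 80), s4 = c(50, 80))
  design <- tibble::tibble(sample = paste0("s", 1:4),
                           condition = rep(c("ctrl", "treat"), each = 2))
  res <- tidy(nb_test(counts, design))
  expect_equal(res$log2_fc, c(0, 0))
  expect_equal(res$status, c("ns", "ns"))
  expect_equal(res$p_value, c(1, 1))
})

test_that("a strong planted effect is recovered as up", {
  sim <- simulate_counts(paste0("f", 1:200), n_reps = 3, base_mean = 500,
                         dispersion = 0.05, fold_changes = c(f1 = 4), seed = 5)
  fit <- nb_test(sim$counts, sim$design)
  res <- tidy(fit)
  expect_equal(res$status[res$feature_id == "f1"], "up")
  expect_equal(res$log2_fc[res$feature_id == "f1"], 2, tolerance = 0.35)
  cls <- classify(fit)
  expect_true("f1" %in% cls$up)
})

test_that("all-zero features are untested and excluded from BH", {
  counts <- tibble::tibble(feature_id = c("z", paste0("f", 1:5)),
                           kind = "gene")
  set.seed(41)
  for (s in paste0("s", 1:6)) counts[[s]] <- c(0, rpois(5, 100))
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           condition = rep(c("ctrl", "treat"), each = 3))
  res <- tidy(nb_test(counts, design))
  expect_equal(res$status[1], "untested")
  expect_true(is.na(res$p_adj[1]))
  # BH computed over the 5 tested features only
  tested <- res[-1, ]
  expect_equal(tested$p_adj, p.adjust(tested$p_value, "BH"))
  # BH invariants
  ord <- order(tested$p_value)
  expect_true(all(diff(tested$p_adj[ord]) >= -1e-12))
  expect_true(all(tested$p_adj <= 1 & tested$p_adj >= tested$p_value - 1e-12))
})

test_that("single-replicate designs need the explicit fallback", {
  counts <- tibble::tibble(feature_id = "a", kind = "gene",
                           s1 = 10, s2 = 12, s3 = 30)
  design <- tibble::tibble(sample = paste0("s", 1:3),
                           condition = c("ctrl", "ctrl", "treat"))
  expect_error(nb_test(counts, design), "replicates")
  fit <- nb_test(counts, design, allow_no_replicates = TRUE)
  expect_true(fit$low_confidence)
})

test_that("classification respects the linear fold-change boundary", {
  res <- tibble::tibble(feature_id = c("a", "b", "c"),
                        log2_fc = c(0.58, 1.0, -1.2),
                        p_adj = c(0.01, 0.049, 0.01))
  cls <- classify(res, fc_cutoff = 1.5, alpha = 0.05)
  expect_false("a" %in% cls$up)   # 0.58 < log2(1.5) ~ 0.585
  expect_true("b" %in% cls$up)
  expect_true("c" %in% cls$down)
  empty <- classify(res[0, ])
  expect_equal(empty, list(up = character(), down = character()))
})

test_that("Welch enrichment matches the closed-form oracle", {
  bait <- tibble::tibble(feature_id = "e1", b1 = 10, b2 = 12, b3 = 11)
  ctrl <- tibble::tibble(feature_id = "e1", c1 = 2, c2 = 3, c3 = 2)
  res <- welch_enrichment(bait, ctrl)
  o <- welch_oracle(c(10, 12, 11), c(2, 3, 2))
  expect_equal(res$p_value, o$p, tolerance = 1e-10)
  expect_true(res$bound)

  # identical sides: nothing bound, p = 1 for the zero-variance case
  same <- welch_enrichment(bait, dplyr::rename(bait, c1 = b1, c2 = b2, c3 = b3))
  expect_false(any(same$bound))

  # fold change of exactly the cutoff is not bound (strict >)
  b2 <- tibble::tibble(feature_id = "e1", b1 = 30, b2 = 29, b3 = 31)
  c2 <- tibble::tibble(feature_id = "e1", c1 = 20, c2 = 19, c3 = 21)
  res2 <- welch_enrichment(b2, c2)
  expect_equal(res2$fold_change, 1.5, tolerance = 1e-12)
  expect_false(res2$bound)
})

test_that("fold-change estimates agree with an established NB implementation", {
  sim <- simulate_counts(paste0("f", 1:300), n_reps = 3, base_mean = 300,
                         dispersion = 0.05,
                         fold_changes = c(f1 = 4, f2 = 0.25), seed = 13)
  ours <- tidy(nb_test(sim$counts, sim$design))

  mat <- as.matrix(sim$counts[, -(1:2)])
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    mat, data.frame(condition = factor(sim$design$condition,
                                       levels = c("ctrl", "treat"))),
    ~condition
  ))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))

  expect_gt(cor(ours$log2_fc, ref$log2FoldChange), 0.95)
  expect_equal(ours$status[1:2], c("up", "down"))
  expect_true(all(ref$padj[1:2] < 0.05))
  # size factors agree with the reference implementation
  expect_equal(unname(size_factors(mat)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
               tolerance = 0.02)
})

test_that("zero variance on both sides with equal means gives p = 1", {
  bait <- tibble::tibble(feature_id = "e1", b1 = 5, b2 = 5)
  ctrl <- tibble::tibble(feature_id = "e1", c1 = 5, c2 = 5)
  expect_equal(welch_enrichment(bait, ctrl)$p_value, 1)
})
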