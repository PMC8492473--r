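mk_genes <- function(tss, chrom = "chr1", ids = NULL) {
  tibble::tibble(
    gene_id = ids %||% sprintf("g%02d", seq_along(tss)),
    chrom = chrom, start = as.integer(tss), end = as.integer(tss) + 1000L,
    strand = "+", tss = as.integer(tss)
  )
}

mk_copy <- function(start, end, strand = "+", id = "c1") {
  tibble::tibble(copy_id = id, family = "f:ERV1:LTR", superfamily = "ERV1",
                 te_class = "LTR", chrom = "chr1", start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

test_that("closest gene minimizes TSS distance with the stated sign rule", {
  genes <- mk_genes(c(1000, 5000))
  # copy [1200,1300): 200 bp from TSS 1000 (upstream of a + copy), 3700 from 5000
  res <- closest_gene(mk_copy(1200, 1300), genes)
  expect_equal(res$gene_id, "g01")
  expect_equal(abs(res$distance), 200L)
  expect_lt(res$distance, 0)  # TSS on the 5' side of the + strand copy
  # same copy on the minus strand flips the sign
  res_m <- closest_gene(mk_copy(1200, 1300, strand = "-"), genes)
  expect_equal(res_m$distance, 200L)
})

test_that("a copy spanning a TSS has distance zero", {
  res <- closest_gene(mk_copy(900, 1100), mk_genes(1000))
  expect_equal(res$distance, 0L)
})

test_that("equidistant ties go to the first gene in sort order", {
  genes <- mk_genes(c(2000, 1000), ids = c("gB", "gA"))
  # copy center at 1500: both TSS 400 bp away from the copy edges
  res <- closest_gene(mk_copy(1400, 1600), genes)
  expect_equal(res$gene_id, "gA")  # sorted by (chrom, start, gene_id)
})

test_that("copies without genes on their chromosome are reported", {
  copy <- mk_copy(100, 200)
  copy$chrom <- "chr9"
  expect_warning(res <- closest_gene(copy, mk_genes(1000)), "unassigned")
  expect_true(is.na(res$gene_id))
})

test_that("the proximity window boundary is inclusive at exactly window bp", {
  w <- 30000L
  # copy end at 1000; TSS at 1000-1+w  -> distance exactly w
  genes <- mk_genes(c(999 + w, 1000 + w), ids = c("at_w", "past_w"))
  copies <- mk_copy(900, 1000)
  prox <- proximal_genes(copies, genes, window = w)
  expect_true("at_w" %in% prox)
  expect_false("past_w" %in% prox)
})

test_that("overlap tests match enumeration oracles", {
  universe <- sprintf("u%03d", 1:100)
  proximal <- universe[1:10]
  degs <- c(universe[6:10], universe[50:64])  # overlap k = 5, n = 20
  res <- observed_overlap_test(proximal, degs, universe)
  expect_equal(res$overlap, 5)
  expect_equal(res$p_hypergeom, hyper_upper_oracle(5, 100, 10, 20),
               tolerance = 1e-10)
  expect_equal(res$p_fisher,
               fisher.test(matrix(c(5, 5, 15, 75), 2))$p.value,
               tolerance = 1e-10)

  # degenerate cases
  expect_equal(observed_overlap_test(proximal, character(), universe)$p_hypergeom, 1)
  all_prox <- observed_overlap_test(universe, degs, universe)
  expect_equal(all_prox$overlap, 20)
  expect_equal(all_prox$p_hypergeom, 1)
})

test_that("resampled background matches the sampling expectation", {
  remaining <- sprintf("r%04d", 1:1000)
  proximal <- remaining[1:100]
  bg <- resampled_background(50, remaining, proximal, n_resamples = 5000,
                             seed = 3)
  expected <- 50 * 100 / 1000
  se <- sd(bg$null_overlaps) / sqrt(5000)
  expect_lt(abs(bg$null_mean - expected), 3 * se)
  # disjoint pool: all-zero null
  bg0 <- resampled_background(10, remaining[101:200], proximal[1:5],
                              n_resamples = 100, seed = 4)
  expect_true(all(bg0$null_overlaps == 0))
  # determinism
  expect_identical(bg$null_overlaps,
                   resampled_background(50, remaining, proximal, 5000,
                                        seed = 3)$null_overlaps)
  expect_error(resampled_background(2000, remaining, proximal), "exceeds")
})

test_that("binomial-vs-null matches enumeration and closed forms", {
  expect_equal(binomial_vs_null(5, 20, 2), binom_upper_oracle(5, 20, 0.1),
               tolerance = 1e-12)
  expect_equal(binomial_vs_null(0, 20, 2), 1)
  # observed = n with p < 1: closed form p^n
  expect_equal(binomial_vs_null(20, 20, 2), 0.1^20, tolerance = 1e-10)
  expect_warning(p0 <- binomial_vs_null(3, 10, 0), "degenerate")
  expect_equal(p0, 0)
  expect_equal(binomial_vs_null(0, 10, 0), 1)
})

test_that("the full proximity test detects planted coupling", {
  gm <- simulate_genome(1, 2e6, 0, seed = 21)
  te <- simulate_te_annotation(gm, 2, 10, c(200L, 400L), seed = 22)
  up_copies <- te$copy_id[te$family == unique(te$family)[1]]
  sim <- simulate_gene_annotation(gm, 400, te, frac_proximal = 0.25,
                                  window = 30000, copies = up_copies,
                                  seed = 23)
  coupled <- unique(sim$truth$gene_id)
  # leave some coupled genes out of the DEG set so the resampling pool
  # still contains proximal genes
  degs <- c(coupled[seq_len(floor(0.8 * length(coupled)))],
            sample(setdiff(sim$genes$gene_id, coupled), 20))
  res <- te_gene_proximity(te[te$copy_id %in% up_copies, ], sim$genes,
                           degs, window = 30000, n_resamples = 1000,
                           seed = 24)
  s <- tidy(res)
  expect_lt(s$p_hypergeom, 0.01)
  expect_lt(s$p_binomial_vs_null, 0.01)
  expect_gte(s$overlap, floor(0.8 * length(coupled)))
  expect_equal(length(res$null_overlaps), 1000)
})
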