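# two single-copy families on one chromosome, used by several tests
two_family_te <- function() {
  tibble::tibble(
    copy_id = c("A_c1", "B_c1"),
    family = c("famA:ERV1:LTR", "famB:L1:LINE"),
    superfamily = c("ERV1", "L1"),
    te_class = c("LTR", "LINE"),
    chrom = "chr1", start = c(0L, 2000L), end = c(1000L, 3000L),
    strand = "+"
  )
}

read_row <- function(id, start, end, n_hits, hit_index = 1L) {
  tibble::tibble(read_id = id, chrom = "chr1", start = as.integer(start),
                 end = as.integer(end), n_hits = n_hits,
                 hit_index = hit_index)
}

test_that("unique reads count toward copies; multi-mappers are excluded", {
  te <- two_family_te()
  reads <- dplyr::bind_rows(
    read_row("u1", 100, 150, 1),
    read_row("m1", 100, 150, 2, 1L),
    read_row("m1", 2100, 2150, 2, 2L)
  )
  cnt <- count_te_copies(reads, te)
  expect_equal(cnt[[3]], c(1L, 0L))
  expect_equal(attr(cnt, "qc")$n_multi_excluded, 1L)
})

test_that("a unique read spanning two copies goes to the larger overlap, ties to the smaller id", {
  te <- tibble::tibble(
    copy_id = c("c2", "c1"), family = "famA:ERV1:LTR",
    superfamily = "ERV1", te_class = "LTR",
    chrom = "chr1", start = c(100L, 200L), end = c(200L, 300L), strand = "+"
  )
  # read [150, 260): 50 bp in c2, 60 bp in c1 -> c1
  cnt <- count_te_copies(read_row("u1", 150, 260, 1), te)
  expect_equal(setNames(cnt[[3]], cnt$feature_id), c(c2 = 0L, c1 = 1L))
  # read [150, 250): 50 bp in both -> lexicographically smaller copy_id c1
  cnt2 <- count_te_copies(read_row("u2", 150, 250, 1), te)
  expect_equal(setNames(cnt2[[3]], cnt2$feature_id), c(c2 = 0L, c1 = 1L))
})

test_that("copy counts equal the brute-force assignment oracle on random reads", {
  set.seed(11)
  gm <- simulate_genome(1, 1e5, 0, seed = 1)
  te <- simulate_te_annotation(gm, 5, 10, c(100L, 300L), seed = 2)
  reads <- rand_intervals(200, n_chroms = 1, chrom_len = 1e5, max_len = 80)
  reads$chrom <- "chr1"
  reads$read_id <- sprintf("r%03d", 1:200)
  reads$n_hits <- 1L
  reads$hit_index <- 1L
  cnt <- count_te_copies(reads, te)

  # oracle: all-pairs overlap widths, max-overlap assignment, min-id ties
  oracle <- setNames(rep(0L, nrow(te)), te$copy_id)
  for (i in seq_len(nrow(reads))) {
    w <- pmin(reads$end[i], te$end) - pmax(reads$start[i], te$start)
    w[reads$chrom[i] != te$chrom] <- 0L
    if (max(w) > 0) {
      cand <- te$copy_id[w == max(w)]
      best <- sort(cand)[1]
      oracle[best] <- oracle[best] + 1L
    }
  }
  expect_equal(setNames(cnt[[3]], cnt$feature_id), oracle)
})

test_that("an ambiguous read splits evenly between two families in uniform mode", {
  te <- two_family_te()
  reads <- dplyr::bind_rows(
    read_row("m1", 100, 150, 2, 1L),
    read_row("m1", 2100, 2150, 2, 2L)
  )
  cnt <- count_te_families(reads, te, mode = "uniform")
  expect_equal(setNames(cnt[[3]], cnt$feature_id),
               c("famA:ERV1:LTR" = 0.5, "famB:L1:LINE" = 0.5))
})

test_that("EM pulls ambiguous mass toward the family with unique support", {
  te <- two_family_te()
  uni <- dplyr::bind_rows(
    purrr::map_dfr(1:9, function(i) read_row(paste0("uA", i), 100 + i, 150 + i, 1)),
    read_row("uB1", 2100, 2150, 1)
  )
  amb <- purrr::map_dfr(1:10, function(i) dplyr::bind_rows(
    read_row(paste0("m", i), 100 + i, 150 + i, 2, 1L),
    read_row(paste0("m", i), 2100 + i, 2150 + i, 2, 2L)
  ))
  cnt <- count_te_families(dplyr::bind_rows(uni, amb), te, mode = "em",
                           em_iters = 50)
  counts <- setNames(cnt[[3]], cnt$feature_id)
  amb_to_A <- counts[["famA:ERV1:LTR"]] - 9
  expect_gt(amb_to_A / 10, 0.8)
  # fixed point of the mixture is exactly 0.9 of the ambiguous mass to A
  expect_equal(amb_to_A / 10, 0.9, tolerance = 1e-4)
  # log-likelihood is non-decreasing
  ll <- attr(cnt, "em")$log_lik
  expect_true(all(diff(ll) >= -1e-10))
})

test_that("uniform and EM agree when there is no ambiguity", {
  te <- two_family_te()
  reads <- dplyr::bind_rows(
    read_row("u1", 100, 150, 1),
    read_row("u2", 2100, 2150, 1)
  )
  u <- count_te_families(reads, te, mode = "uniform")
  e <- count_te_families(reads, te, mode = "em")
  expect_equal(u[[3]], e[[3]], tolerance = 1e-10)
})

test_that("read mass is conserved including the non-TE sink", {
  set.seed(21)
  gm <- simulate_genome(1, 1e5, 0, seed = 3)
  te <- simulate_te_annotation(gm, 4, 8, c(100L, 300L), seed = 4)
  reads <- simulate_te_reads(te, unique_rate = 3, n_multi = 40,
                             hits_per_multi = 3, seed = 5)
  # add reads that overlap no copy at all
  stray <- purrr::map_dfr(1:7, function(i) {
    tibble::tibble(read_id = paste0("stray", i), chrom = "chr1",
                   start = 0L, end = 10L, n_hits = 1L, hit_index = 1L)
  })
  # place strays in a guaranteed TE-free spot
  gap <- teresurge:::gaps_intervals(te, gm$chrom_sizes)
  gap <- gap[gap$end - gap$start >= 20, ][1, ]
  stray$start <- gap$start; stray$end <- gap$start + 10L

  for (mode in c("uniform", "em")) {
    fam <- count_te_families(dplyr::bind_rows(reads, stray), te, mode = mode)
    total <- sum(fam[[3]]) + attr(fam, "qc")$sink_mass
    expect_equal(total, attr(fam, "n_reads_assigned"), tolerance = 1e-8)
  }
})

test_that("unique-read copy counts never exceed family totals", {
  gm <- simulate_genome(1, 1e5, 0, seed = 6)
  te <- simulate_te_annotation(gm, 3, 10, c(100L, 200L), seed = 7)
  reads <- simulate_te_reads(te, unique_rate = 4, n_multi = 30, seed = 8)
  copies <- count_te_copies(reads, te)
  fams <- count_te_families(reads, te, mode = "uniform")
  per_family_copy <- tapply(copies[[3]], te$family[match(copies$feature_id, te$copy_id)], sum)
  fam_counts <- setNames(fams[[3]], fams$feature_id)
  expect_true(all(per_family_copy <= fam_counts[names(per_family_copy)] + 1e-9))
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  te <- two_family_te()
  gm <- genome_model(tibble::tibble(chrom = "chr1", length = 10000L))
  reads <- dplyr::bind_rows(
    read_row("u1", 100, 150, 1),
    tibble::tibble(read_id = "bad", chrom = "chrUn", start = 5L, end = 50L,
                   n_hits = 1L, hit_index = 1L)
  )
  expect_warning(cnt <- count_te_copies(reads, te, genome = gm), "skipping")
  expect_equal(attr(cnt, "qc")$n_unknown_chrom, 1L)
  expect_equal(sum(cnt[[3]]), 1L)
})
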