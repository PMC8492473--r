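# Independent brute-force oracles used across tests. These deliberately use
# naive all-pairs / sweep algorithms, not the package's interval machinery.

rand_intervals <- function(n, n_chroms = 2, chrom_len = 1e5, max_len = 500,
                           min_len = 1) {
  starts <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1L
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  tibble::tibble(
    chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
    start = starts,
    end = starts + lens
  )
}

# O(n*m) all-pairs overlap oracle (>= 1 bp shared, half-open intervals)
brute_overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(query_idx = integer(), subject_idx = integer()))
  }
  grid <- expand.grid(query_idx = seq_len(nrow(a)),
                      subject_idx = seq_len(nrow(b)))
  keep <- a$chrom[grid$query_idx] == b$chrom[grid$subject_idx] &
    a$start[grid$query_idx] < b$end[grid$subject_idx] &
    b$start[grid$subject_idx] < a$end[grid$query_idx]
  out <- grid[keep, , drop = FALSE]
  out <- out[order(out$query_idx, out$subject_idx), , drop = FALSE]
  tibble::tibble(query_idx = as.integer(out$query_idx),
                 subject_idx = as.integer(out$subject_idx))
}

# union-of-intervals oracle by linear sweep (bookended intervals fuse)
brute_merge <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, , drop = FALSE]
    xi <- xi[order(xi$start, xi$end), , drop = FALSE]
    cur_s <- xi$start[1]; cur_e <- xi$end[1]
    for (i in seq_len(nrow(xi))[-1]) {
      if (xi$start[i] <= cur_e) {
        cur_e <- max(cur_e, xi$end[i])
      } else {
        out[[length(out) + 1]] <- c(ch, cur_s, cur_e)
        cur_s <- xi$start[i]; cur_e <- xi$end[i]
      }
    }
    out[[length(out) + 1]] <- c(ch, cur_s, cur_e)
  }
  tibble::tibble(
    chrom = vapply(out, `[`, "", 1),
    start = as.integer(vapply(out, `[`, "", 2)),
    end = as.integer(vapply(out, `[`, "", 3))
  )
}

# exact binomial upper tail by direct summation of the pmf
binom_upper_oracle <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

binom_lower_oracle <- function(k, n, p) {
  sum(choose(n, 0:k) * p^(0:k) * (1 - p)^(n - (0:k)))
}

# hypergeometric upper tail P(X >= k) by direct enumeration
hyper_upper_oracle <- function(k, N, K, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs) / choose(N, n))
}

# Welch statistic/df/p from the textbook formulas
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# paired t from the closed-form formula on the differences
paired_t_oracle <- function(a, b) {
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t_stat, df = length(d) - 1,
       p = 2 * pt(-abs(t_stat), length(d) - 1))
}

# closed-form expected overlap events under uniform per-chromosome
# placement of each padded copy: sum over copies and peaks of
# (#start positions overlapping the peak) / (#feasible start positions)
expected_shuffle_events <- function(padded, genome, peaks) {
  free <- teresurge:::gaps_intervals(genome$excluded, genome$chrom_sizes)
  sapply(split(seq_len(nrow(padded)), padded$family), function(idx) {
    total <- 0
    for (i in idx) {
      fc <- free[free$chrom == padded$chrom[i], , drop = FALSE]
      len <- padded$end[i] - padded$start[i]
      cap <- pmax(0, fc$end - fc$start - len + 1)
      n_valid <- sum(cap)
      pk <- peaks[peaks$chrom == padded$chrom[i], , drop = FALSE]
      for (j in seq_len(nrow(pk))) {
        # feasible starts s with s < pk$end and s + len > pk$start
        lo <- pk$start[j] - len + 1; hi <- pk$end[j] - 1
        n_hit <- 0
        for (g in seq_len(nrow(fc))) {
          gs <- fc$start[g]; ge <- fc$end[g] - len  # last feasible start
          a <- max(gs, lo); b <- min(ge, hi)
          if (b >= a) n_hit <- n_hit + (b - a + 1)
        }
        total <- total + n_hit / n_valid
      }
    }
    total
  })
}
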