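#' Construct a genome model
#'
#' A genome model bundles chromosome sizes with the excluded regions
#' (assembly gaps, blacklist regions, the mitochondrial contig and similar)
#' that are barred from random placement and interval shuffling. Excluded
#' regions are normalized to a disjoint, sorted set on construction.
#'
#' @param chrom_sizes Tibble with columns `chrom` and `length` (bp).
#' @param excluded Tibble of intervals (`chrom`, `start`, `end`) to exclude
#'   from shuffling and placement; may be empty.
#' @return An object of class `genome_model`: a list with elements
#'   `chrom_sizes` and `excluded` (both tibbles).
#' @examples
#' gm <- genome_model(tibble::tibble(chrom = "chr1", length = 1e6L))
#' @export
genome_model <- function(chrom_sizes,
                         excluded = tibble(chrom = character(), start = integer(),
                                           end = integer())) {
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "length") %in% names(chrom_sizes)))
  chrom_sizes <- as_tibble(chrom_sizes)
  if (any(chrom_sizes$length <= 0)) abort("chromosome lengths must be > 0")
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicate chromosome names")
  excluded <- as_tibble(excluded)
  validate_intervals(excluded, chrom_sizes, what = "excluded regions")
  excluded <- reduce_intervals(excluded)
  structure(
    list(chrom_sizes = chrom_sizes, excluded = excluded),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chrom_sizes), " chromosome(s), ",
      sum(x$chrom_sizes$length), " bp total, ",
      nrow(x$excluded), " excluded region(s) (",
      covered_bp(x$excluded), " bp)\n", sep = "")
  invisible(x)
}

#' Default analysis parameters
#'
#' Collects the tunable thresholds of the pipeline with the defaults used
#' throughout: a linear fold-change cutoff of 1.5 and adjusted-p threshold
#' 0.05 for differential calls, a +/-30 kb TSS window for TE-copy/gene
#' proximity, +/-1 kb TE padding and 1,000 shuffles for the accessibility
#' enrichment test, 10,000 resamples for the proximity background, a 300 bp
#' minimum peak size, and the Tn5 insertion coordinate shift of +4 bp
#' (plus strand) / -5 bp (minus strand).
#'
#' @param fc_cutoff Linear fold-change threshold (> 1).
#' @param alpha Adjusted-p threshold in (0, 1).
#' @param proximity_window Half-width in bp of the TSS window.
#' @param te_pad Padding in bp added to each side of a TE copy.
#' @param n_shuffles_atac Number of TE-placement shuffles for the null.
#' @param n_resamples_proximity Number of gene resamples for the background.
#' @param min_peak_len Minimum retained peak length in bp.
#' @param tn5_shift Integer vector `c(plus, minus)` of strand-specific shifts.
#' @param rng_seed Integer seed recorded for provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_cutoff = 1.5,
                            alpha = 0.05,
                            proximity_window = 30000L,
                            te_pad = 1000L,
                            n_shuffles_atac = 1000L,
                            n_resamples_proximity = 10000L,
                            min_peak_len = 300L,
                            tn5_shift = c(4L, -5L),
                            rng_seed = 1L) {
  stopifnot(
    fc_cutoff > 1, alpha > 0, alpha < 1,
    proximity_window > 0, te_pad >= 0,
    n_shuffles_atac > 0, n_resamples_proximity > 0,
    min_peak_len >= 0, length(tn5_shift) == 2
  )
  structure(
    list(
      fc_cutoff = fc_cutoff, alpha = alpha,
      proximity_window = as.integer(proximity_window),
      te_pad = as.integer(te_pad),
      n_shuffles_atac = as.integer(n_shuffles_atac),
      n_resamples_proximity = as.integer(n_resamples_proximity),
      min_peak_len = as.integer(min_peak_len),
      tn5_shift = as.integer(tn5_shift),
      rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_config"
  )
}

#' Simulate a genome with excluded regions
#'
#' Builds a toy genome of `n_chroms` chromosomes of `chrom_len` bp each and
#' carves out non-overlapping excluded regions covering approximately
#' `excluded_fraction` of every chromosome (ten equal-length blocks placed
#' uniformly at random without overlap), emulating the gap/blacklist/chrM
#' mask of a real assembly.
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_len Chromosome length in bp.
#' @param excluded_fraction Fraction of each chromosome to exclude, in
#'   `[0, 0.5)`; larger values would leave too little shuffle space.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return A [genome_model()].
#' @examples
#' gm <- simulate_genome(2, 1e6, 0.1, seed = 7)
#' @export
simulate_genome <- function(n_chroms, chrom_len, excluded_fraction = 0, seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_len > 0)
  if (excluded_fraction < 0 || excluded_fraction >= 0.5) {
    abort("excluded_fraction must be in [0, 0.5): larger masks leave no shuffle space")
  }
  chrom_len <- as.integer(chrom_len)
  chrom_sizes <- tibble(
    chrom = paste0("chr", seq_len(n_chroms)),
    length = chrom_len
  )
  if (excluded_fraction == 0) {
    return(genome_model(chrom_sizes))
  }
  n_blocks <- 10L
  block_len <- max(1L, as.integer(round(excluded_fraction * chrom_len / n_blocks)))
  excluded <- withr::with_seed(seed, {
    purrr::map_dfr(chrom_sizes$chrom, function(ch) {
      place_disjoint(
        n = n_blocks, len = block_len,
        gaps = tibble(chrom = ch, start = 0L, end = chrom_len)
      )
    })
  })
  genome_model(chrom_sizes, excluded)
}

# Place n non-overlapping intervals of length `len` uniformly inside `gaps`
# (a disjoint interval set), by sequential exact-uniform draws over the
# remaining feasible start positions. Errors when space runs out.
place_disjoint <- function(n, len, gaps) {
  out <- vector("list", n)
  free <- gaps
  for (i in seq_len(n)) {
    pos <- sample_start_uniform(free, len)
    if (is.null(pos)) {
      abort(sprintf("cannot place interval %d of %d (length %d): no space left", i, n, len))
    }
    out[[i]] <- tibble(chrom = pos$chrom, start = pos$start, end = pos$start + len)
    # remove the placed interval from the free space
    free <- subtract_intervals(free, out[[i]])
  }
  bind_rows(out)
}

# Uniform draw of a start position such that [start, start+len) fits inside
# one of the disjoint `free` intervals. Returns NULL when infeasible.
sample_start_uniform <- function(free, len) {
  cap <- pmax(0, free$end - free$start - len + 1)
  total <- sum(cap)
  if (total == 0) return(NULL)
  pick <- sample.int(total, 1L)
  idx <- findInterval(pick - 1, cumsum(cap), left.open = FALSE) + 1L
  offset <- pick - c(0, cumsum(cap))[idx] - 1L
  list(chrom = free$chrom[idx], start = as.integer(free$start[idx] + offset))
}

# Set-difference of disjoint interval set `a` minus interval set `b`.
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  res <- GenomicRanges::setdiff(as_granges(a), as_granges(b), ignore.strand = TRUE)
  granges_to_tibble(GenomicRanges::sort(res, ignore.strand = TRUE))
}
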