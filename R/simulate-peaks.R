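# Start-coordinate space helpers: an interval [s, e) in "start space" means
# any start position in it yields a peak of length L with the property the
# set encodes (fits in free space / overlaps a padded target).

starts_fitting <- function(free, len) {
  keep <- free$end - free$start >= len
  tibble(chrom = free$chrom[keep], start = free$start[keep],
         end = free$end[keep] - len + 1L)
}

starts_overlapping <- function(targets, len) {
  if (nrow(targets) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  reduce_intervals(tibble(
    chrom = targets$chrom,
    start = pmax(0L, targets$start - len + 1L),
    end = targets$end
  ))
}

intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  res <- GenomicRanges::intersect(as_granges(a), as_granges(b), ignore.strand = TRUE)
  granges_to_tibble(GenomicRanges::sort(res, ignore.strand = TRUE))
}

#' Simulate accessibility peaks with controlled TE-family enrichment
#'
#' Places `n_peaks` fixed-length peaks in the genome, avoiding excluded
#' regions, such that the probability a peak overlaps the `pad`-extended
#' span of a copy of an enriched family equals `enrichment_factor` times
#' the probability under uniform placement (capped at 1). With
#' `enrichment_factor = 1` placement is exactly uniform over all allowed
#' start positions. The construction samples start coordinates from the
#' exact hit/miss start-position sets, so the stated overlap probability
#' holds by design rather than asymptotically.
#'
#' @param genome A [genome_model()].
#' @param te_annotation TE copy tibble.
#' @param enriched_families Character vector of family labels to enrich.
#' @param enrichment_factor Multiplier (>= 1) on the uniform hit probability.
#' @param n_peaks Number of peaks.
#' @param peak_len Peak length in bp.
#' @param pad Padding in bp applied to TE copies when defining "nearby".
#' @param seed Integer seed.
#' @return List with `peaks` (tibble: `chrom`, `start`, `end`, `name`,
#'   `score`) and `truth` (list with `enriched_families` and the realized
#'   uniform hit probability `p_uniform`).
#' @export
simulate_peaks <- function(genome, te_annotation, enriched_families = character(),
                           enrichment_factor = 1, n_peaks = 100L,
                           peak_len = 400L, pad = 1000L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), enrichment_factor >= 1,
            n_peaks >= 0, peak_len >= 1, pad >= 0)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric())
  if (n_peaks == 0) {
    return(list(peaks = empty,
                truth = list(enriched_families = enriched_families, p_uniform = NA_real_)))
  }
  free <- gaps_intervals(genome$excluded, genome$chrom_sizes)
  valid <- starts_fitting(free, as.integer(peak_len))
  n_valid <- sum(valid$end - valid$start)
  if (n_valid == 0) abort("no placeable space for peaks of this length")

  padded <- pad_te_intervals(
    filter(te_annotation, .data$family %in% enriched_families),
    pad = pad, genome = genome
  )
  hit <- intersect_intervals(valid, starts_overlapping(padded, as.integer(peak_len)))
  miss <- {
    m <- subtract_intervals(valid, hit)
    m[m$end > m$start, , drop = FALSE]
  }
  n_hit <- sum(hit$end - hit$start)
  p_uniform <- n_hit / n_valid
  p_target <- min(1, enrichment_factor * p_uniform)

  peaks <- withr::with_seed(seed, {
    take_hit <- runif(n_peaks) < p_target
    if (any(take_hit) && n_hit == 0) abort("no start positions near enriched families")
    if (any(!take_hit) && nrow(miss) == 0) {
      abort("no start positions away from enriched families")
    }
    starts <- purrr::map(take_hit, function(h) {
      sample_start_uniform(
        if (h) hit else miss,
        1L  # start space already encodes peak length
      )
    })
    tibble(
      chrom = purrr::map_chr(starts, "chrom"),
      start = purrr::map_int(starts, "start"),
      end = purrr::map_int(starts, "start") + as.integer(peak_len),
      name = sprintf("peak_%04d", seq_len(n_peaks)),
      score = round(runif(n_peaks, 50, 1000), 1)
    )
  })
  list(peaks = arrange(peaks, .data$chrom, .data$start),
       truth = list(enriched_families = enriched_families, p_uniform = p_uniform))
}
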