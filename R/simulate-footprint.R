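#' Simulate Tn5 insertion profiles around motif sites
#'
#' Generates per-site, per-strand, per-position insertion counts over a
#' window of `flank` bp on each side of a `motif_len` bp motif. Counts are
#' Poisson with rate `background_rate` outside the motif and
#' `background_rate * (1 - footprint_depth)` inside it, so `footprint_depth
#' = 0` gives a flat profile in expectation and `footprint_depth = 1` a
#' fully protected (zero-insertion) motif core — the signature a bound
#' transcription factor leaves in ATAC-seq data.
#'
#' @param n_sites Number of motif sites.
#' @param flank Flank width in bp on each side of the motif.
#' @param motif_len Motif length in bp.
#' @param background_rate Expected insertions per bp per strand outside the
#'   motif (>= 0).
#' @param footprint_depth Fractional protection inside the motif, in `[0, 1]`.
#' @param seed Integer seed.
#' @return An object of class `footprint_profiles`: a list with `counts`
#'   (tibble: `site_id`, `strand`, `pos`, `count`; `pos` is relative to the
#'   motif start, so the motif spans `0 .. motif_len - 1`), `motif_len` and
#'   `flank`.
#' @examples
#' fp <- simulate_insertion_profiles(50, flank = 50, motif_len = 10,
#'                                   background_rate = 0.5,
#'                                   footprint_depth = 0.8, seed = 1)
#' @export
simulate_insertion_profiles <- function(n_sites, flank = 100L, motif_len = 15L,
                                        background_rate = 0.5,
                                        footprint_depth = 0, seed = 1L) {
  stopifnot(n_sites >= 1, flank >= 1, motif_len >= 1)
  if (background_rate < 0) abort("background_rate must be >= 0")
  if (footprint_depth < 0 || footprint_depth > 1) {
    abort("footprint_depth must lie in [0, 1]")
  }
  pos <- seq(-flank, motif_len + flank - 1L)
  in_motif <- pos >= 0 & pos < motif_len
  rate <- ifelse(in_motif, background_rate * (1 - footprint_depth), background_rate)

  counts <- withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      site_id = sprintf("site%04d", seq_len(n_sites)),
      strand = c("+", "-"),
      pos = pos
    )
    grid$count <- rpois(nrow(grid), rep(rate, times = n_sites * 2L))
    grid
  })
  structure(
    list(counts = counts, motif_len = as.integer(motif_len),
         flank = as.integer(flank)),
    class = "footprint_profiles"
  )
}

#' @export
print.footprint_profiles <- function(x, ...) {
  cat("<footprint_profiles> ", dplyr::n_distinct(x$counts$site_id), " site(s), motif ",
      x$motif_len, " bp, flank ", x$flank, " bp, ",
      sum(x$counts$count), " insertions\n", sep = "")
  invisible(x)
}
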