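#' Merge two peak sets into consensus peaks
#'
#' Concatenates the two sets and fuses overlapping or bookended intervals
#' (gap of 0 bp merges, matching the default behaviour of interval merge
#' tools). The result is disjoint and sorted by (`chrom`, `start`).
#'
#' @param a,b Peak tibbles (`chrom`, `start`, `end`, further columns
#'   dropped).
#' @return Tibble of disjoint consensus intervals with a `name` column
#'   (`consensus_0001`, ...).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
#' b <- tibble::tibble(chrom = "chr1", start = 200L, end = 300L)
#' merge_peaks(a, b)  # one interval [100, 300)
#' @export
merge_peaks <- function(a, b) {
  validate_intervals(a, what = "peak set a")
  validate_intervals(b, what = "peak set b")
  merged <- reduce_intervals(bind_rows(
    select(a, "chrom", "start", "end"),
    select(b, "chrom", "start", "end")
  ))
  if (nrow(merged)) merged$name <- sprintf("consensus_%04d", seq_len(nrow(merged)))
  else merged$name <- character()
  merged
}

#' Split consensus peaks into gained, lost and common
#'
#' Classifies each consensus peak by which input peak set(s) it overlaps
#' (>= 1 bp; bookended intervals do not count as overlapping): peaks
#' overlapping the later time point but not baseline are `gained`, the
#' converse are `lost`, and peaks overlapping both are `common`. The three
#' sets partition the consensus.
#'
#' @param consensus Consensus peaks, normally `merge_peaks(peaks_t,
#'   peaks_0)`; every consensus peak must overlap at least one input peak.
#' @param peaks_t Peak set of the later time point.
#' @param peaks_0 Baseline peak set.
#' @return List of tibbles `gained`, `lost`, `common` (rows of `consensus`).
#' @export
gained_lost <- function(consensus, peaks_t, peaks_0) {
  validate_intervals(consensus, what = "consensus")
  in_t <- overlaps_any(consensus, peaks_t)
  in_0 <- overlaps_any(consensus, peaks_0)
  if (any(!in_t & !in_0)) {
    abort("consensus contains peaks overlapping neither input set; was it built by merge_peaks() on these inputs?")
  }
  list(
    gained = consensus[in_t & !in_0, , drop = FALSE],
    lost = consensus[!in_t & in_0, , drop = FALSE],
    common = consensus[in_t & in_0, , drop = FALSE]
  )
}

overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  hits <- overlap_pairs(query, subject)
  seq_len(nrow(query)) %in% hits$query_idx
}

#' Discard peaks shorter than a minimum length
#'
#' Retains peaks with `end - start >= min_len`; the boundary is inclusive,
#' so a peak of exactly `min_len` bp is kept.
#'
#' @param peaks Peak tibble.
#' @param min_len Minimum length in bp (default 300).
#' @return Filtered tibble.
#' @export
filter_min_length <- function(peaks, min_len = 300L) {
  stopifnot(min_len >= 0)
  validate_intervals(peaks, what = "peaks")
  filter(peaks, .data$end - .data$start >= min_len)
}

#' Differential accessibility over consensus peaks
#'
#' Applies the negative binomial Wald test ([nb_test()]) to a matrix of
#' per-sample read counts over consensus peaks; peaks called `up` are the
#' significantly gained regions, `down` the significantly lost ones.
#'
#' @param peak_counts Counts tibble (`feature_id` = consensus peak name,
#'   sample columns).
#' @param design Tibble (`sample`, `condition`); baseline condition first.
#' @param ... Passed on to [nb_test()].
#' @return An `nb_fit` object (see [nb_test()]).
#' @export
peak_count_significance <- function(peak_counts, design, ...) {
  if (nrow(peak_counts) == 0) {
    return(structure(
      list(results = tibble(feature_id = character(), kind = character(),
                            base_mean = numeric(), log2_fc = numeric(),
                            se = numeric(), stat = numeric(),
                            p_value = numeric(), p_adj = numeric(),
                            dispersion = numeric(), status = character()),
           size_factors = numeric(), design = design,
           reference = NA_character_, alternative = NA_character_,
           fc_cutoff = 1.5, alpha = 0.05,
           normalization = "median_ratios", low_confidence = FALSE),
      class = "nb_fit"
    ))
  }
  if (!"kind" %in% names(peak_counts)) {
    peak_counts <- mutate(peak_counts, kind = "peak", .after = "feature_id")
  }
  nb_test(peak_counts, design, ...)
}
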