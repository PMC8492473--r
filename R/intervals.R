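#' Genomic interval conventions
#'
#' All interval tables in teresurge are plain tibbles with at least the
#' columns `chrom` (character), `start` and `end` (0-based, half-open, so a
#' one-base feature has `end == start + 1`), and optionally `strand`
#' (`"+"`, `"-"` or `"."`). This matches the BED convention, so BED files
#' round-trip without coordinate shifts. Conversion to the 1-based closed
#' convention of [GenomicRanges::GRanges] happens only inside overlap
#' machinery and is never user-visible.
#'
#' @name interval-conventions
NULL

# Validate an interval tibble; optionally check bounds against chrom sizes.
validate_intervals <- function(x, chrom_sizes = NULL, what = "interval table") {
  if (!is.data.frame(x)) {
    abort(paste0(what, " must be a data frame"))
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols)) {
    abort(paste0(what, " lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$end <= x$start)) {
    abort(paste0(what, ": need 0 <= start < end for every row"))
  }
  if (!is.null(chrom_sizes)) {
    sz <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    unknown <- setdiff(unique(x$chrom), names(sz))
    if (length(unknown)) {
      abort(paste0(what, ": unknown chromosome(s): ", paste(unknown, collapse = ", ")))
    }
    if (any(x$end > sz[x$chrom])) {
      abort(paste0(what, ": intervals exceed chromosome bounds"))
    }
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Index pairs (query_idx, subject_idx) of >= 1 bp overlaps, strand-blind.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query_idx = integer(), subject_idx = integer()))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges(query), as_granges(subject),
    minoverlap = 1L, ignore.strand = TRUE
  )
  tibble(
    query_idx = S4Vectors::queryHits(hits),
    subject_idx = S4Vectors::subjectHits(hits)
  )
}

# bp of overlap for given index pairs
overlap_widths <- function(query, subject, pairs) {
  pmin(query$end[pairs$query_idx], subject$end[pairs$subject_idx]) -
    pmax(query$start[pairs$query_idx], subject$start[pairs$subject_idx])
}

# Fuse overlapping/bookended intervals into a disjoint sorted set (per chrom).
reduce_intervals <- function(x) {
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = 1L, ignore.strand = TRUE)
  out <- granges_to_tibble(GenomicRanges::sort(gr, ignore.strand = TRUE))
  arrange(out, .data$chrom, .data$start)
}

# Complement of `x` within chromosomes (gaps usable for placement).
gaps_intervals <- function(x, chrom_sizes) {
  covered <- reduce_intervals(x)
  purrr::pmap_dfr(chrom_sizes, function(chrom, length) {
    cx <- covered[covered$chrom == chrom, , drop = FALSE]
    bounds <- c(0L, rbind(cx$start, cx$end), length)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    tibble(chrom = chrom, start = as.integer(starts[keep]), end = as.integer(ends[keep]))
  })
}

# Total bp covered by a (possibly overlapping) interval set.
covered_bp <- function(x) {
  r <- reduce_intervals(x)
  if (nrow(r) == 0) 0 else sum(r$end - r$start)
}
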