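# Plain-text readers/writers for the pipeline's tabular formats. All BED
# output is 0-based half-open, matching the internal convention, so
# coordinates round-trip unchanged.

#' Read and write chromosome sizes
#'
#' Two-column TSV (`chrom`, `length`) as used by genome browsers.
#'
#' @param path File path.
#' @return `read_chrom_sizes()` returns a tibble (`chrom`, `length`).
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = "ci", progress = FALSE)
}

#' @rdname read_chrom_sizes
#' @param genome A [genome_model()] or a `chrom`/`length` tibble.
#' @export
write_chrom_sizes <- function(genome, path) {
  sizes <- if (inherits(genome, "genome_model")) genome$chrom_sizes else genome
  readr::write_tsv(sizes, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' Reads BED3-BED6 into the package's interval tibble (0-based half-open,
#' like BED itself).
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  ncol_bed <- ncol(first)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol_bed, 6))]
  types <- substr("ciicdc", 1, min(ncol_bed, 6))
  out <- readr::read_tsv(path, col_names = cols, col_types = types,
                         progress = FALSE)
  validate_intervals(out, what = path)
  out
}

#' @rdname read_bed
#' @param x Interval tibble; columns beyond BED6 are dropped.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED requires a contiguous prefix of the 6 standard columns
  keep <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% cols) keep <- c(keep, extra) else break
  }
  readr::write_tsv(x[, keep, drop = FALSE], path, col_names = FALSE)
  invisible(path)
}

#' Read and write TE copy annotations as BED
#'
#' The BED name field encodes `copy_id|family:superfamily:class`, keeping
#' the copy/family hierarchy in a standard format.
#'
#' @param path File path.
#' @return `read_te_bed()` returns the TE copy tibble used across the
#'   package.
#' @export
read_te_bed <- function(path) {
  raw <- read_bed(path)
  if (!"name" %in% names(raw)) abort("TE BED needs a name field")
  parts <- strsplit(raw$name, "|", fixed = TRUE)
  fam <- purrr::map_chr(parts, 2)
  fam_parts <- strsplit(fam, ":", fixed = TRUE)
  tibble(
    copy_id = purrr::map_chr(parts, 1),
    family = fam,
    superfamily = purrr::map_chr(fam_parts, function(p) p[2] %||% NA_character_),
    te_class = purrr::map_chr(fam_parts, function(p) p[3] %||% NA_character_),
    chrom = raw$chrom, start = raw$start, end = raw$end,
    strand = raw$strand %||% "."
  )
}

#' @rdname read_te_bed
#' @param te_annotation TE copy tibble.
#' @export
write_te_bed <- function(te_annotation, path) {
  bed <- tibble(
    chrom = te_annotation$chrom,
    start = te_annotation$start,
    end = te_annotation$end,
    name = paste0(te_annotation$copy_id, "|", te_annotation$family),
    score = 0,
    strand = te_annotation$strand %||% "."
  )
  write_bed(bed, path)
}

#' Read and write narrowPeak files
#'
#' The 10-column ENCODE narrowPeak format; `score` is preserved, the
#' statistics columns are kept on read and filled with placeholders on
#' write when absent.
#'
#' @param path File path.
#' @return `read_narrowpeak()` returns a peak tibble.
#' @export
read_narrowpeak <- function(path) {
  out <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "signal", "p", "q", "summit"),
    col_types = "ciicdcdddi", progress = FALSE
  )
  validate_intervals(out, what = path)
  out
}

#' @rdname read_narrowpeak
#' @param peaks Peak tibble.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks[["name"]] %||% sprintf("peak_%04d", seq_len(n)),
    score = peaks[["score"]] %||% 0,
    strand = ".",
    signal = peaks[["signal"]] %||% 0,
    p = peaks[["p"]] %||% -1,
    q = peaks[["q"]] %||% -1,
    summit = peaks[["summit"]] %||% -1L
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write count matrices
#'
#' TSV with `feature_id`, `kind`, then one column per sample.
#'
#' @param path File path.
#' @return `read_counts()` returns the counts tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = "c", kind = "c", .default = "d"
  ), progress = FALSE)
}

#' @rdname read_counts
#' @param counts Counts tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Write and read simulation ground truth
#'
#' Flat key-value text (`key<TAB>value`), vectors comma-joined, so truth
#' survives as a plain, diffable file.
#'
#' @param truth Named list of character/numeric vectors.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  lines <- purrr::imap_chr(truth, function(v, k) {
    paste0(k, "\t", paste(v, collapse = ","))
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readr::read_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- purrr::map(parts, function(p) strsplit(p[2] %||% "", ",")[[1]])
  names(out) <- purrr::map_chr(parts, 1)
  out
}
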