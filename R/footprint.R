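#' Tn5-shift fragment ends into insertion positions
#'
#' Converts sequenced fragment ends into Tn5 insertion events with the
#' ATAC-seq coordinate correction: plus-strand ends are shifted by +4 bp
#' (insertion at `start + 4`), minus-strand ends by -5 bp (insertion at
#' `end - 5`), centring each event on the Tn5 dyad. Events shifted outside
#' their chromosome are dropped and tallied in the `qc` attribute, so event
#' counts are conserved up to the reported drops.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`, `strand` (one row
#'   per fragment end to process).
#' @param genome Optional [genome_model()] used to drop out-of-bounds
#'   events.
#' @return Tibble (`chrom`, `pos`, `strand`) of insertion events with a
#'   `qc` attribute (`n_dropped`).
#' @export
shift_insertions <- function(fragments, genome = NULL) {
  if (nrow(fragments) == 0) {
    out <- tibble(chrom = character(), pos = integer(), strand = character())
    attr(out, "qc") <- list(n_dropped = 0L)
    return(out)
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(fragments)))
  pos <- ifelse(fragments$strand == "+",
                fragments$start + 4L,
                fragments$end - 5L)
  out <- tibble(chrom = fragments$chrom, pos = as.integer(pos),
                strand = fragments$strand)
  n_dropped <- 0L
  keep <- out$pos >= 0
  if (!is.null(genome)) {
    lens <- setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
    keep <- keep & out$pos < lens[out$chrom]
  }
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  attr(out, "qc") <- list(n_dropped = n_dropped)
  out
}

#' Build per-site insertion profiles around motif sites
#'
#' Collects insertion events into per-site, per-strand, per-position counts
#' over `[-flank, motif_len + flank)` relative to each motif start. All
#' sites must share one width (the motif length).
#'
#' @param insertions Tibble (`chrom`, `pos`, `strand`) as from
#'   [shift_insertions()].
#' @param sites Motif site tibble (`chrom`, `start`, `end`), equal widths.
#' @param flank Flank width in bp.
#' @return A `footprint_profiles` object (see
#'   [simulate_insertion_profiles()]).
#' @export
insertion_profiles <- function(insertions, sites, flank = 100L) {
  stopifnot(flank > 0)
  validate_intervals(sites, what = "motif sites")
  if (nrow(sites) == 0) abort("no motif sites supplied")
  widths <- unique(sites$end - sites$start)
  if (length(widths) != 1) abort("motif sites must share one width")
  motif_len <- widths
  flank <- as.integer(flank)
  if (!"site_id" %in% names(sites)) {
    sites$site_id <- sprintf("site%04d", seq_len(nrow(sites)))
  }
  pos_range <- seq(-flank, motif_len + flank - 1L)

  windows <- tibble(chrom = sites$chrom,
                    start = pmax(0L, sites$start - flank),
                    end = sites$end + flank)
  ins_iv <- tibble(chrom = insertions$chrom, start = insertions$pos,
                   end = insertions$pos + 1L)
  pairs <- overlap_pairs(ins_iv, windows)
  counted <- tibble(
    site_id = sites$site_id[pairs$subject_idx],
    strand = insertions$strand[pairs$query_idx],
    pos = insertions$pos[pairs$query_idx] - sites$start[pairs$subject_idx]
  ) %>%
    filter(.data$pos >= -flank, .data$pos < motif_len + flank) %>%
    count(.data$site_id, .data$strand, .data$pos, name = "count")

  grid <- tidyr::expand_grid(site_id = sites$site_id, strand = c("+", "-"),
                             pos = pos_range)
  counts <- left_join(grid, counted, by = c("site_id", "strand", "pos")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  structure(list(counts = counts, motif_len = as.integer(motif_len),
                 flank = flank),
            class = "footprint_profiles")
}

#' Average strand-split insertion profile across sites
#'
#' Per-position mean insertion count across sites, strands kept separate
#' (the classic red/blue footprint profile). `normalize = "per-bp-rate"`
#' rescales each strand's profile to sum to 1 across the window.
#'
#' @param profiles A `footprint_profiles` object, or an insertions tibble
#'   (then `sites` and `flank` are required and are passed to
#'   [insertion_profiles()]).
#' @param sites,flank Used only when `profiles` is an insertions tibble.
#' @param normalize `"none"` or `"per-bp-rate"`.
#' @return Tibble (`pos`, `strand`, `value`); `pos` is relative to the
#'   motif start.
#' @export
aggregate_profile <- function(profiles, sites = NULL, flank = NULL,
                              normalize = c("none", "per-bp-rate")) {
  normalize <- match.arg(normalize)
  if (!inherits(profiles, "footprint_profiles")) {
    if (is.null(sites) || is.null(flank)) {
      abort("supply `sites` and `flank` when passing raw insertions")
    }
    profiles <- insertion_profiles(profiles, sites, flank)
  }
  n_sites <- dplyr::n_distinct(profiles$counts$site_id)
  if (n_sites == 0) abort("profile set has no sites")
  out <- profiles$counts %>%
    group_by(.data$strand, .data$pos) %>%
    summarise(value = sum(.data$count) / n_sites, .groups = "drop")
  if (normalize == "per-bp-rate") {
    out <- out %>%
      group_by(.data$strand) %>%
      mutate(value = if (sum(.data$value) > 0) .data$value / sum(.data$value)
             else .data$value) %>%
      ungroup()
  }
  arrange(out, .data$strand, .data$pos)
}

#' Plot an average insertion profile
#'
#' @param profile Tibble from [aggregate_profile()].
#' @param motif_len Optional motif length to shade the motif span.
#' @return A ggplot with sense insertions in red and antisense in blue.
#' @export
plot_insertion_profile <- function(profile, motif_len = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$pos, y = .data$value,
                                             colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(`+` = "#c0392b", `-` = "#2980b9"),
                                 labels = c(`+` = "sense", `-` = "antisense")) +
    ggplot2::labs(x = "position relative to motif start",
                  y = "mean insertions per site", colour = NULL)
  if (!is.null(motif_len)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = motif_len,
                               ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  p
}

#' Footprint occupancy scores
#'
#' Per-site flank-ratio occupancy score: with `C` insertions in the motif
#' span and `L`, `R` insertions in the `flank_width` bp windows immediately
#' left and right of it (both strands pooled),
#' `fos = (C + 1) / max(L, 1) + (C + 1) / max(R, 1)`.
#' Lower scores mean deeper protection (a more occupied motif). The
#' pseudocounts keep the score defined for empty windows.
#'
#' @param profiles A `footprint_profiles` object.
#' @param flank_width Flank window width in bp (default 35); must not
#'   exceed the profile flank.
#' @return Tibble (`site_id`, `center_count`, `left_count`, `right_count`,
#'   `fos`).
#' @export
fos <- function(profiles, flank_width = 35L) {
  stopifnot(inherits(profiles, "footprint_profiles"), flank_width >= 1)
  if (flank_width > profiles$flank) {
    abort("flank_width exceeds the flank stored in the profiles")
  }
  ml <- profiles$motif_len
  profiles$counts %>%
    mutate(zone = dplyr::case_when(
      .data$pos >= 0 & .data$pos < ml ~ "center",
      .data$pos >= -flank_width & .data$pos < 0 ~ "left",
      .data$pos >= ml & .data$pos < ml + flank_width ~ "right",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$zone)) %>%
    group_by(.data$site_id, .data$zone) %>%
    summarise(n = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "zone", values_from = "n",
                       values_fill = 0L) %>%
    mutate(
      center_count = .data$center,
      left_count = .data$left,
      right_count = .data$right,
      fos = (.data$center + 1) / pmax(.data$left, 1) +
        (.data$center + 1) / pmax(.data$right, 1)
    ) %>%
    select("site_id", "center_count", "left_count", "right_count", "fos")
}

#' Paired comparison of footprint occupancy between conditions
#'
#' Log2-transforms the per-site occupancy scores of two conditions paired
#' by site and applies a two-tailed paired t-test, treating each site as
#' the same chromosomal region in both conditions. A negative mean log2
#' difference (a - b) means condition a has deeper footprints.
#'
#' @param fos_a,fos_b Tibbles from [fos()] with matching `site_id`s.
#' @return Object of class `fos_comparison`; [tidy()]/[glance()] give the
#'   one-row summary (`mean_log2_diff`, `t`, `df`, `p_value`, `n_sites`).
#' @export
compare_fos <- function(fos_a, fos_b) {
  joined <- inner_join(
    select(fos_a, "site_id", fos_a = "fos"),
    select(fos_b, "site_id", fos_b = "fos"),
    by = "site_id"
  )
  if (nrow(joined) < 2) abort("need at least 2 paired sites")
  d <- log2(joined$fos_a) - log2(joined$fos_b)
  n <- length(d)
  if (all(d == 0)) {
    t_stat <- 0; p <- 1
  } else {
    tt <- t.test(log2(joined$fos_a), log2(joined$fos_b), paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(summary = tibble(mean_log2_diff = mean(d), t = t_stat,
                          df = n - 1L, p_value = p, n_sites = n),
         pairs = joined),
    class = "fos_comparison"
  )
}

#' @export
print.fos_comparison <- function(x, ...) {
  s <- x$summary
  cat("<fos_comparison> ", s$n_sites, " paired sites; mean log2 diff ",
      signif(s$mean_log2_diff, 3), ", t = ", signif(s$t, 3),
      ", p = ", signif(s$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname compare_fos
#' @param x A `fos_comparison` object.
#' @param ... Unused.
#' @method tidy fos_comparison
#' @export
tidy.fos_comparison <- function(x, ...) x$summary

#' @rdname compare_fos
#' @method glance fos_comparison
#' @export
glance.fos_comparison <- function(x, ...) x$summary

#' Paired occupancy-score scatter
#'
#' @param object A `fos_comparison` object.
#' @param ... Unused.
#' @return A ggplot of per-site log2 scores, condition b vs a.
#' @method autoplot fos_comparison
#' @export
autoplot.fos_comparison <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = log2(.data$fos_a), y = log2(.data$fos_b))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::labs(x = "log2 FOS (condition a)", y = "log2 FOS (condition b)")
}
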