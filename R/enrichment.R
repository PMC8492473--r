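#' Pad TE copies on both sides
#'
#' Extends every TE copy by `pad` bp upstream and downstream (the +/-1 kb
#' neighbourhood used when asking whether an accessibility peak lies "near"
#' a TE), clipping to chromosome bounds when a genome is supplied.
#'
#' @param te_annotation TE copy tibble.
#' @param pad Padding in bp (>= 0).
#' @param genome Optional [genome_model()] for clipping.
#' @return The annotation with widened `start`/`end`.
#' @export
pad_te_intervals <- function(te_annotation, pad = 1000L, genome = NULL) {
  stopifnot(pad >= 0)
  out <- mutate(te_annotation,
                start = pmax(0L, .data$start - as.integer(pad)),
                end = .data$end + as.integer(pad))
  if (!is.null(genome)) {
    lens <- setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
    out <- mutate(out, end = pmin(.data$end, as.integer(lens[.data$chrom])))
  }
  out
}

#' Count peak-copy overlap events per TE family
#'
#' For each family, the number of (peak, copy) pairs with >= 1 bp overlap;
#' one peak overlapping k copies of a family contributes k events, which
#' gives the statistic a closed-form expectation under uniform placement.
#' `count = "distinct_peaks"` instead counts peaks overlapping at least one
#' copy of the family.
#'
#' @param peaks Peak tibble.
#' @param padded_te Padded TE annotation (see [pad_te_intervals()]).
#' @param count Event counting mode.
#' @return Named numeric vector, one entry per family present in
#'   `padded_te` (zero-filled).
#' @export
observed_overlap <- function(peaks, padded_te,
                             count = c("events", "distinct_peaks")) {
  count <- match.arg(count)
  families <- unique(padded_te$family)
  out <- setNames(rep(0, length(families)), families)
  if (nrow(peaks) == 0 || nrow(padded_te) == 0) return(out)
  pairs <- overlap_pairs(peaks, padded_te)
  if (nrow(pairs) == 0) return(out)
  pairs$family <- padded_te$family[pairs$subject_idx]
  if (count == "distinct_peaks") {
    pairs <- distinct(pairs, .data$query_idx, .data$family)
  }
  tab <- table(pairs$family)
  out[names(tab)] <- as.numeric(tab)
  out
}

#' Shuffled-placement null for peak-TE overlap
#'
#' Builds the empirical null distribution of per-family overlap counts by
#' relocating every padded TE copy uniformly at random within the allowed
#' space (its own chromosome minus excluded regions), preserving copy
#' lengths exactly, and recounting overlaps with the fixed peak set.
#' Shuffled copies may overlap one another. Chromosome assignment is
#' preserved so the null respects per-chromosome TE abundance.
#'
#' @param padded_te Padded TE annotation.
#' @param genome A [genome_model()].
#' @param peaks Peak tibble (held fixed).
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed.
#' @param count Overlap counting mode, as in [observed_overlap()].
#' @return Numeric matrix `n_shuffles` x families of null overlap counts.
#' @export
shuffle_te_null <- function(padded_te, genome, peaks, n_shuffles = 1000L,
                            seed = 1L, count = c("events", "distinct_peaks")) {
  count <- match.arg(count)
  stopifnot(inherits(genome, "genome_model"), n_shuffles >= 1)
  families <- unique(padded_te$family)
  if (nrow(padded_te) == 0) {
    return(matrix(0, nrow = n_shuffles, ncol = 0))
  }
  free <- gaps_intervals(genome$excluded, genome$chrom_sizes)
  lens <- padded_te$end - padded_te$start
  n_copies <- nrow(padded_te)

  # per-copy feasible start space on its own chromosome
  copy_space <- purrr::map(seq_len(n_copies), function(i) {
    fc <- free[free$chrom == padded_te$chrom[i], , drop = FALSE]
    sp <- starts_fitting(fc, lens[i])
    if (nrow(sp) == 0 || sum(sp$end - sp$start) == 0) {
      abort(sprintf("no shuffle space for a %d bp interval on %s",
                    lens[i], padded_te$chrom[i]))
    }
    sp
  })

  null_mat <- withr::with_seed(seed, {
    # draw all starts up front: copies x shuffles
    starts <- matrix(0L, nrow = n_copies, ncol = n_shuffles)
    for (i in seq_len(n_copies)) {
      sp <- copy_space[[i]]
      cap <- sp$end - sp$start
      total <- sum(cap)
      picks <- sample.int(total, n_shuffles, replace = TRUE)
      idx <- findInterval(picks - 1, cumsum(cap)) + 1L
      starts[i, ] <- sp$start[idx] + (picks - c(0, cumsum(cap))[idx] - 1L)
    }
    shuffled <- tibble(
      chrom = rep(padded_te$chrom, times = n_shuffles),
      start = as.integer(starts),
      end = as.integer(starts) + rep(lens, times = n_shuffles),
      family = rep(padded_te$family, times = n_shuffles),
      shuffle = rep(seq_len(n_shuffles), each = n_copies)
    )
    stopifnot(all(shuffled$end - shuffled$start == rep(lens, times = n_shuffles)))
    out <- matrix(0, nrow = n_shuffles, ncol = length(families),
                  dimnames = list(NULL, families))
    if (nrow(peaks) > 0) {
      pairs <- overlap_pairs(peaks, shuffled)
      if (nrow(pairs) > 0) {
        pairs$family <- shuffled$family[pairs$subject_idx]
        pairs$shuffle <- shuffled$shuffle[pairs$subject_idx]
        if (count == "distinct_peaks") {
          pairs <- distinct(pairs, .data$query_idx, .data$family, .data$shuffle)
        }
        tab <- table(pairs$shuffle, pairs$family)
        out[as.integer(rownames(tab)), colnames(tab)] <- as.matrix(tab)
      }
    }
    out
  })
  null_mat
}

#' Binomial and hypergeometric enrichment test against a shuffle null
#'
#' Compares an observed overlap count to its shuffled-placement null. The
#' binomial p-value treats each of the `n_peaks` peaks as a trial with
#' success probability `null_mean / n_peaks`; the upper tail is reported
#' for observed counts above the null mean (enrichment) and the lower tail
#' below it (depletion). The hypergeometric p-value discretizes the genome
#' into padded-family vs other bp (urn of `genome_bp`, `family_bp`
#' successes, `peak_bp` draws, `overlap_bp` observed successes). Direction
#' is assigned from the binomial tail at `alpha`.
#'
#' @param observed Observed overlap count.
#' @param null Numeric vector of null overlap counts.
#' @param n_peaks Number of peaks (binomial trials).
#' @param genome_bp,family_bp,peak_bp,overlap_bp Totals for the
#'   hypergeometric 2x2 (optional; `NA`s give `p_hypergeometric = NA`).
#' @param alpha Significance level for direction assignment.
#' @return One-row tibble: `observed`, `null_mean`, `null_sd`, `p_binomial`,
#'   `p_hypergeometric`, `direction`.
#' @export
enrichment_test <- function(observed, null, n_peaks,
                            genome_bp = NA, family_bp = NA, peak_bp = NA,
                            overlap_bp = NA, alpha = 0.05) {
  stopifnot(length(null) >= 1, n_peaks >= 0)
  null_mean <- mean(null)
  null_sd <- sd(null)
  if (n_peaks == 0 || (null_mean == 0 && observed == 0)) {
    return(tibble(observed = observed, null_mean = null_mean,
                  null_sd = null_sd, p_binomial = 1,
                  p_hypergeometric = NA_real_, direction = "ns"))
  }
  p_hat <- min(null_mean / n_peaks, 1)
  p_up <- pbinom(observed - 1, n_peaks, p_hat, lower.tail = FALSE)
  p_down <- pbinom(observed, n_peaks, p_hat)
  p_binomial <- if (observed >= null_mean) p_up else p_down

  p_hyper <- NA_real_
  if (!anyNA(c(genome_bp, family_bp, peak_bp, overlap_bp))) {
    p_hyper <- if (observed >= null_mean) {
      phyper(overlap_bp - 1, family_bp, genome_bp - family_bp, peak_bp,
             lower.tail = FALSE)
    } else {
      phyper(overlap_bp, family_bp, genome_bp - family_bp, peak_bp)
    }
  }
  direction <- if (p_binomial < alpha) {
    if (observed >= null_mean) "enriched" else "depleted"
  } else "ns"
  tibble(observed = observed, null_mean = null_mean, null_sd = null_sd,
         p_binomial = p_binomial, p_hypergeometric = p_hyper,
         direction = direction)
}

#' TE-family enrichment in accessible chromatin
#'
#' Full per-family test: pads TE copies by `pad` bp, counts observed
#' peak-copy overlap events, builds the shuffled-placement null
#' ([shuffle_te_null()]) and applies [enrichment_test()] per family,
#' including the bp-resolution hypergeometric variant.
#'
#' @param peaks Peak tibble (e.g. the gained set for one time point).
#' @param te_annotation Unpadded TE copy tibble.
#' @param genome A [genome_model()].
#' @param pad Padding in bp (default 1 kb).
#' @param n_shuffles Number of shuffles (default 1000).
#' @param alpha Significance level for direction calls.
#' @param seed Integer seed.
#' @param count Overlap counting mode, see [observed_overlap()].
#' @return Object of class `te_enrichment`; [tidy()] gives one row per
#'   family (`family`, `n_copies`, `observed`, `null_mean`, `null_sd`,
#'   `p_binomial`, `p_hypergeometric`, `direction`).
#' @export
te_family_enrichment <- function(peaks, te_annotation, genome, pad = 1000L,
                                 n_shuffles = 1000L, alpha = 0.05, seed = 1L,
                                 count = c("events", "distinct_peaks")) {
  count <- match.arg(count)
  padded <- pad_te_intervals(te_annotation, pad = pad, genome = genome)
  obs <- observed_overlap(peaks, padded, count = count)
  null_mat <- shuffle_te_null(padded, genome, peaks, n_shuffles = n_shuffles,
                              seed = seed, count = count)
  genome_bp <- sum(genome$chrom_sizes$length)
  peak_bp <- covered_bp(peaks)

  rows <- purrr::map_dfr(names(obs), function(fam) {
    fam_rows <- padded[padded$family == fam, , drop = FALSE]
    fam_bp <- covered_bp(fam_rows)
    ov_pairs <- overlap_pairs(peaks, fam_rows)
    ov_bp <- if (nrow(ov_pairs)) {
      covered_bp(tibble(
        chrom = peaks$chrom[ov_pairs$query_idx],
        start = pmax(peaks$start[ov_pairs$query_idx], fam_rows$start[ov_pairs$subject_idx]),
        end = pmin(peaks$end[ov_pairs$query_idx], fam_rows$end[ov_pairs$subject_idx])
      ))
    } else 0
    bind_cols(
      tibble(family = fam, n_copies = nrow(fam_rows)),
      enrichment_test(unname(obs[fam]), null_mat[, fam], nrow(peaks),
                      genome_bp = genome_bp, family_bp = fam_bp,
                      peak_bp = peak_bp, overlap_bp = ov_bp, alpha = alpha)
    )
  })
  structure(
    list(table = rows, null = null_mat, pad = pad, n_shuffles = n_shuffles,
         alpha = alpha, count = count),
    class = "te_enrichment"
  )
}

#' @export
print.te_enrichment <- function(x, ...) {
  cat("<te_enrichment> ", nrow(x$table), " families, ", x$n_shuffles,
      " shuffles, pad ", x$pad, " bp; ",
      sum(x$table$direction == "enriched"), " enriched, ",
      sum(x$table$direction == "depleted"), " depleted\n", sep = "")
  invisible(x)
}

#' @rdname te_family_enrichment
#' @param x A `te_enrichment` object.
#' @param ... Unused.
#' @method tidy te_enrichment
#' @export
tidy.te_enrichment <- function(x, ...) x$table

#' @rdname te_family_enrichment
#' @method glance te_enrichment
#' @export
glance.te_enrichment <- function(x, ...) {
  tibble(
    n_families = nrow(x$table),
    n_enriched = sum(x$table$direction == "enriched"),
    n_depleted = sum(x$table$direction == "depleted"),
    n_shuffles = x$n_shuffles,
    pad = x$pad,
    alpha = x$alpha
  )
}

#' Observed vs null overlap per family
#'
#' @param object A `te_enrichment` object.
#' @param ... Unused.
#' @return A ggplot comparing observed overlap counts to the shuffle null
#'   (mean +/- 2 sd) per family.
#' @method autoplot te_enrichment
#' @export
autoplot.te_enrichment <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$null_mean,
      ymin = pmax(0, .data$null_mean - 2 * .data$null_sd),
      ymax = .data$null_mean + 2 * .data$null_sd
    ), colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, colour = .data$direction),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(enriched = "#c0392b",
                                            depleted = "#2980b9", ns = "grey30")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "peak-copy overlap events", colour = NULL)
}

#' Intersect enrichment calls with differential TE families
#'
#' Joins the accessibility-enrichment table with the up/down sets from the
#' expression test and flags families that are simultaneously differentially
#' expressed and enriched or depleted in the peak set — the families whose
#' transcriptional change is accompanied by a chromatin-accessibility
#' change.
#'
#' @param enrichment A `te_enrichment` object or its tidy table.
#' @param de_families List with character vectors `up` and `down` (as from
#'   [classify()]).
#' @return The enrichment table with `de_status` and logical `flagged`.
#' @export
cross_with_de <- function(enrichment, de_families) {
  tab <- if (inherits(enrichment, "te_enrichment")) enrichment$table else enrichment
  mutate(tab,
    de_status = dplyr::case_when(
      .data$family %in% de_families$up ~ "up",
      .data$family %in% de_families$down ~ "down",
      TRUE ~ "ns"
    ),
    flagged = .data$de_status != "ns" & .data$direction != "ns"
  )
}
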