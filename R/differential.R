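# Extract the numeric sample matrix from a counts tibble
# (feature_id, kind, <sample columns>) and its feature metadata.
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "feature_id" %in% names(counts))
  meta_cols <- intersect(c("feature_id", "kind"), names(counts))
  sample_cols <- setdiff(names(counts), meta_cols)
  if (!length(sample_cols)) abort("counts table has no sample columns")
  mat <- as.matrix(counts[, sample_cols, drop = FALSE])
  if (!is.numeric(mat)) abort("sample columns must be numeric")
  if (any(mat < 0)) abort("negative counts")
  rownames(mat) <- counts$feature_id
  list(mat = mat,
       meta = tibble(feature_id = counts$feature_id,
                     kind = if ("kind" %in% names(counts)) counts$kind else "gene"))
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against the geometric-mean
#' pseudo-reference: for each sample the factor is the median across
#' features of the ratio of its count to the feature's geometric mean over
#' all samples. Only features with nonzero counts in every sample enter the
#' median; when no such feature exists the function falls back to
#' total-count ratios with a warning.
#'
#' @param counts Counts tibble (`feature_id`, optional `kind`, one numeric
#'   column per sample) or a numeric matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b"), s1 = c(10, 20), s2 = c(20, 40))
#' size_factors(m)
#' @export
size_factors <- function(counts) {
  mat <- if (is.matrix(counts)) counts else counts_matrix(counts)$mat
  if (ncol(mat) == 1) return(setNames(1, colnames(mat)))
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos)) {
    warn("no feature has nonzero counts in all samples; using total-count ratios")
    totals <- colSums(mat)
    if (any(totals == 0)) abort("cannot normalize: a sample has zero total counts")
    sf <- totals / exp(mean(log(totals)))
    return(setNames(sf, colnames(mat)))
  }
  kept <- mat[all_pos, , drop = FALSE]
  gm <- exp(rowMeans(log(kept)))
  sf <- apply(kept / gm, 2, median)
  setNames(sf, colnames(mat))
}

resolve_design <- function(design, sample_names) {
  if (is.data.frame(design)) {
    stopifnot(all(c("sample", "condition") %in% names(design)))
    cond <- setNames(as.character(design$condition), design$sample)
  } else {
    cond <- setNames(as.character(design), names(design) %||% sample_names)
  }
  missing <- setdiff(sample_names, names(cond))
  if (length(missing)) abort(paste0("no condition for sample(s): ",
                                    paste(missing, collapse = ", ")))
  cond <- cond[sample_names]
  levels <- unique(cond)
  if (length(levels) != 2) abort("exactly two conditions are required")
  list(condition = cond, ref = levels[1], alt = levels[2])
}

#' Negative binomial Wald test for differential abundance
#'
#' Tests each feature for a difference in mean normalized counts between two
#' conditions under a negative binomial model (`Var = mu + dispersion *
#' mu^2`). Dispersion is estimated per feature by the method of moments on
#' within-group variances (pooled across the two groups), then shrunk
#' toward the across-feature mean with a prior weight of 10 residual df
#' (and floored at 1e-8) — the usual information-sharing remedy for
#' 2-3-replicate designs. The Wald statistic on the log fold change is
#' referred to a t distribution with `n1 + n2 - 2 + 10` degrees of freedom,
#' crediting the shared prior. P-values are adjusted by
#' Benjamini-Hochberg across tested features; features with zero counts in
#' every sample are reported as `untested` and excluded from the adjustment.
#' The reported `log2_fc` is second condition over first (in `design`
#' order).
#'
#' @param counts Counts tibble (`feature_id`, optional `kind`, sample
#'   columns).
#' @param design Tibble (`sample`, `condition`) or a named character vector;
#'   exactly two conditions, the first being the reference.
#' @param fc_cutoff,alpha Thresholds used to label `up`/`down` status
#'   (linear fold change and adjusted p).
#' @param pairwise_norm If `TRUE`, size factors are estimated on this
#'   comparison's samples only from the submitted matrix (the "pairwise"
#'   normalization used for TE copy matrices); the default is the same
#'   computation — the flag exists so callers can record the choice when the
#'   submitted matrix is a subset of a larger one.
#' @param allow_no_replicates If a condition has a single sample, fail
#'   unless this is `TRUE`, in which case dispersion is estimated across
#'   both conditions jointly (inflated by any true signal) and results are
#'   flagged `low_confidence`.
#' @param size_factors_override Optional precomputed size factors.
#' @return An object of class `nb_fit`. Use [tidy()] for the per-feature
#'   table (`feature_id`, `kind`, `base_mean`, `log2_fc`, `se`, `stat`,
#'   `p_value`, `p_adj`, `status`) and [glance()] for a one-row summary.
#' @export
nb_test <- function(counts, design, fc_cutoff = 1.5, alpha = 0.05,
                    pairwise_norm = FALSE, allow_no_replicates = FALSE,
                    size_factors_override = NULL) {
  cm <- counts_matrix(counts)
  mat <- cm$mat
  des <- resolve_design(design, colnames(mat))
  g1 <- des$condition == des$ref
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  low_confidence <- FALSE
  if (n1 < 2 || n2 < 2) {
    if (!allow_no_replicates) {
      abort("a condition has fewer than 2 replicates (set allow_no_replicates = TRUE to proceed with a pooled-dispersion heuristic)")
    }
    low_confidence <- TRUE
  }

  sf <- size_factors_override %||% size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")

  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  base_mean <- rowMeans(norm)
  tested <- rowSums(mat) > 0

  if (!low_confidence) {
    v1 <- apply(norm[, g1, drop = FALSE], 1, var)
    v2 <- apply(norm[, g2, drop = FALSE], 1, var)
    a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
    a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA_real_)
    w1 <- ifelse(is.na(a1), 0, n1 - 1)
    w2 <- ifelse(is.na(a2), 0, n2 - 1)
    disp_raw <- (w1 * dplyr::coalesce(a1, 0) + w2 * dplyr::coalesce(a2, 0)) /
      pmax(w1 + w2, 1)
    # shrink the noisy per-feature estimate toward the across-feature mean;
    # the prior contributes `prior_df` pseudo-replicate df to the reference t
    df_res <- n1 + n2 - 2
    prior_df <- 10
    prior_disp <- mean(pmax(disp_raw[tested], 0), na.rm = TRUE)
    if (!is.finite(prior_disp)) prior_disp <- 0
    disp_raw <- (prior_df * prior_disp + df_res * disp_raw) /
      (prior_df + df_res)
    df <- df_res + prior_df
  } else {
    v_all <- apply(norm, 1, var)
    m_all <- rowMeans(norm)
    disp_raw <- ifelse(m_all > 0, (v_all - m_all) / m_all^2, 0)
    df <- max(n1 + n2 - 2, 1)
  }
  dispersion <- pmax(disp_raw, 1e-8)

  # delta-method variance of log(mean-hat) per group under NB
  s1 <- pmax(m1, 0.5)
  s2 <- pmax(m2, 0.5)
  se_log <- sqrt((1 / s1 + dispersion) / n1 + (1 / s2 + dispersion) / n2)
  log2_fc <- ifelse(m1 == m2, 0, log2(s2 / s1))
  stat <- ifelse(se_log > 0, (log(s2) - log(s1)) / se_log, 0)
  p_value <- 2 * pt(-abs(stat), df = df)
  p_value[!tested] <- NA_real_

  p_adj <- rep(NA_real_, length(p_value))
  p_adj[tested] <- p.adjust(p_value[tested], method = "BH")

  status <- rep("untested", length(p_value))
  lfc_cut <- log2(fc_cutoff)
  status[tested] <- "ns"
  status[tested & log2_fc >= lfc_cut & p_adj < alpha] <- "up"
  status[tested & log2_fc <= -lfc_cut & p_adj < alpha] <- "down"

  results <- bind_cols(
    cm$meta,
    tibble(base_mean = unname(base_mean), log2_fc = unname(log2_fc),
           se = unname(se_log) / log(2), stat = unname(stat),
           p_value = unname(p_value), p_adj = unname(p_adj),
           dispersion = unname(dispersion), status = status)
  )
  structure(
    list(
      results = results,
      size_factors = sf,
      design = tibble(sample = colnames(mat), condition = des$condition),
      reference = des$ref, alternative = des$alt,
      fc_cutoff = fc_cutoff, alpha = alpha,
      normalization = if (pairwise_norm) "median_ratios_pairwise" else "median_ratios",
      low_confidence = low_confidence
    ),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  n <- table(factor(x$results$status, levels = c("up", "down", "ns", "untested")))
  cat("<nb_fit> ", nrow(x$results), " features (", x$alternative, " vs ",
      x$reference, "): ", n[["up"]], " up, ", n[["down"]], " down, ",
      n[["ns"]], " ns, ", n[["untested"]], " untested",
      if (x$low_confidence) " [low confidence: pooled dispersion]" else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname nb_test
#' @param x An `nb_fit` object.
#' @param ... Unused.
#' @method tidy nb_fit
#' @export
tidy.nb_fit <- function(x, ...) x$results

#' @rdname nb_test
#' @method glance nb_fit
#' @export
glance.nb_fit <- function(x, ...) {
  st <- x$results$status
  tibble(
    n_features = nrow(x$results),
    n_tested = sum(st != "untested"),
    n_up = sum(st == "up"),
    n_down = sum(st == "down"),
    fc_cutoff = x$fc_cutoff,
    alpha = x$alpha,
    reference = x$reference,
    alternative = x$alternative,
    low_confidence = x$low_confidence
  )
}

#' MA plot of a differential test
#'
#' @param object An `nb_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nb_fit
#' @export
autoplot.nb_fit <- function(object, ...) {
  d <- filter(object$results, .data$status != "untested")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$base_mean, y = .data$log2_fc,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * log2(object$fc_cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change",
                  colour = NULL)
}

#' Threshold differential results into up/down sets
#'
#' Pure filter applying the linear fold-change cutoff (on `|log2_fc| >=
#' log2(fc_cutoff)`) and the adjusted-p threshold.
#'
#' @param results Tidy results tibble (from [tidy()] on an `nb_fit`) with
#'   columns `feature_id`, `log2_fc`, `p_adj`.
#' @param fc_cutoff Linear fold-change threshold.
#' @param alpha Adjusted-p threshold.
#' @return List with character vectors `up` and `down`.
#' @export
classify <- function(results, fc_cutoff = 1.5, alpha = 0.05) {
  if (inherits(results, "nb_fit")) results <- results$results
  if (nrow(results) == 0) return(list(up = character(), down = character()))
  lfc <- log2(fc_cutoff)
  ok <- !is.na(results$p_adj) & results$p_adj < alpha
  list(
    up = results$feature_id[ok & results$log2_fc >= lfc],
    down = results$feature_id[ok & results$log2_fc <= -lfc]
  )
}

#' Welch-test enrichment of bait over control counts
#'
#' Per-element two-sample Welch (unequal variance) t-test comparing bait
#' pull-down counts to control, as used for calling elements significantly
#' bound in cross-linking pull-down data. An element is `bound` when its
#' fold change (bait mean over control mean) is strictly greater than
#' `fc_cutoff` and the unadjusted Welch p-value is below `p_cutoff`.
#' Normalization defaults to none; `normalize = "total"` rescales each
#' sample to the mean library size first. The choice is recorded in the
#' `normalization` attribute of the result.
#'
#' @param counts_bait,counts_control Counts tibbles (`feature_id`, sample
#'   columns) with identical features.
#' @param fc_cutoff Linear fold-change threshold (strict inequality).
#' @param p_cutoff Raw p-value threshold.
#' @param normalize `"none"` or `"total"`.
#' @return Tibble (`feature_id`, `mean_bait`, `mean_control`, `fold_change`,
#'   `p_value`, `bound`).
#' @export
welch_enrichment <- function(counts_bait, counts_control, fc_cutoff = 1.5,
                             p_cutoff = 0.05, normalize = c("none", "total")) {
  normalize <- match.arg(normalize)
  b <- counts_matrix(counts_bait)
  c_ <- counts_matrix(counts_control)
  if (!identical(b$meta$feature_id, c_$meta$feature_id)) {
    abort("bait and control must list the same features in the same order")
  }
  if (ncol(b$mat) < 2 || ncol(c_$mat) < 2) {
    abort("need >= 2 replicates on each side for the Welch test")
  }
  bm <- b$mat; cm2 <- c_$mat
  if (normalize == "total") {
    all_tot <- c(colSums(bm), colSums(cm2))
    target <- mean(all_tot)
    bm <- sweep(bm, 2, colSums(bm) / target, "/")
    cm2 <- sweep(cm2, 2, colSums(cm2) / target, "/")
  }
  res <- purrr::map_dfr(seq_len(nrow(bm)), function(i) {
    x <- bm[i, ]; y <- cm2[i, ]
    p <- if (var(x) == 0 && var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      t.test(x, y, var.equal = FALSE)$p.value
    }
    tibble(mean_bait = mean(x), mean_control = mean(y), p_value = p)
  })
  out <- bind_cols(tibble(feature_id = b$meta$feature_id), res) %>%
    mutate(
      fold_change = .data$mean_bait / pmax(.data$mean_control, .Machine$double.eps),
      bound = .data$fold_change > fc_cutoff & .data$p_value < p_cutoff
    ) %>%
    select("feature_id", "mean_bait", "mean_control", "fold_change",
           "p_value", "bound")
  attr(out, "normalization") <- normalize
  out
}
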