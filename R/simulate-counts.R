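#' Simulate a two-condition count matrix
#'
#' Draws feature-by-sample counts from a negative binomial model with
#' mean/dispersion parameterization (`Var = mu + dispersion * mu^2`), the
#' model family used by count-based differential tools for RNA-seq and
#' ATAC-seq. Condition "treat" means are the baseline means multiplied by
#' the per-feature fold change; `dispersion = 0` degrades to Poisson.
#' Per-sample library size factors scale every mean, letting normalization
#' be exercised.
#'
#' @param features Character vector of feature ids, or a tibble with columns
#'   `feature_id` and `kind` (one of `"gene"`, `"te_family"`, `"te_copy"`).
#' @param n_reps Replicates per condition.
#' @param base_mean Baseline expected count (> 0); scalar or per-feature.
#' @param dispersion NB dispersion (>= 0); scalar or per-feature.
#' @param fold_changes Named numeric vector of linear fold changes
#'   (treat/ctrl) for a subset of features; unnamed features default to 1.
#' @param lib_size_factors Per-sample scale factors, length `2 * n_reps`
#'   (ctrl samples first) or scalar.
#' @param seed Integer seed.
#' @return List with `counts` (tibble: `feature_id`, `kind`, one column per
#'   sample), `design` (tibble: `sample`, `condition` with levels
#'   `ctrl`/`treat`) and `truth` (tibble of features with fold change != 1).
#' @examples
#' sim <- simulate_counts(paste0("g", 1:100), n_reps = 3, base_mean = 50,
#'                        dispersion = 0.05, fold_changes = c(g1 = 4), seed = 1)
#' @export
simulate_counts <- function(features, n_reps, base_mean = 100,
                            dispersion = 0.05, fold_changes = NULL,
                            lib_size_factors = 1, seed = 1L) {
  if (is.character(features)) {
    features <- tibble(feature_id = features, kind = "gene")
  }
  stopifnot(is.data.frame(features), "feature_id" %in% names(features))
  if (!"kind" %in% names(features)) features$kind <- "gene"
  if (anyDuplicated(features$feature_id)) abort("duplicate feature ids")
  if (any(base_mean <= 0)) abort("base_mean must be > 0")
  if (any(dispersion < 0)) abort("dispersion must be >= 0")
  if (n_reps < 0) abort("n_reps must be >= 0")
  n_feat <- nrow(features)

  fc <- rep(1, n_feat)
  names(fc) <- features$feature_id
  if (!is.null(fold_changes)) {
    if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes)))) {
      abort("fold_changes must be a named vector")
    }
    unknown <- setdiff(names(fold_changes), features$feature_id)
    if (length(unknown)) abort(paste0("unknown feature in fold_changes: ",
                                      paste(unknown, collapse = ", ")))
    if (any(fold_changes <= 0)) abort("fold changes must be > 0")
    fc[names(fold_changes)] <- fold_changes
  }

  design <- tibble(
    sample = c(sprintf("ctrl_r%d", seq_len(n_reps)),
               sprintf("treat_r%d", seq_len(n_reps))),
    condition = rep(c("ctrl", "treat"), each = n_reps)
  )
  n_samp <- nrow(design)
  sf <- rep_len(lib_size_factors, max(n_samp, 1))[seq_len(n_samp)]
  if (n_samp > 0 && any(sf <= 0)) abort("lib_size_factors must be > 0")

  base_mean <- rep_len(base_mean, n_feat)
  dispersion <- rep_len(dispersion, n_feat)

  counts <- withr::with_seed(seed, {
    mat <- matrix(0L, nrow = n_feat, ncol = n_samp,
                  dimnames = list(features$feature_id, design$sample))
    for (j in seq_len(n_samp)) {
      mu <- sf[j] * base_mean * (if (design$condition[j] == "treat") fc else 1)
      pois <- dispersion == 0
      col <- integer(n_feat)
      if (any(pois)) col[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        col[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / dispersion[!pois])
      }
      mat[, j] <- col
    }
    mat
  })

  out <- bind_cols(
    select(features, "feature_id", "kind"),
    as_tibble(counts)
  )
  truth <- tibble(feature_id = features$feature_id, fold_change = unname(fc)) %>%
    filter(.data$fold_change != 1)
  list(counts = out, design = design, truth = truth)
}
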