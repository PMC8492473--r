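#' Run the full synthetic-data pipeline
#'
#' Generates a complete synthetic study — genome, TE annotation, genes with
#' TE-proximity coupling, two-condition count matrices with planted fold
#' changes, baseline and stimulated peak sets with one peak-enriched TE
#' family, and footprint profiles with condition-dependent protection —
#' then runs every analysis stage on it: family/copy differential tests,
#' consensus/gained/lost peak construction, peak-count significance,
#' TE-family accessibility enrichment crossed with expression, the
#' TE-copy/gene proximity test, and the paired footprint-occupancy
#' comparison. The recorded ground truth makes each stage's calls
#' checkable.
#'
#' Default sizes (2 chromosomes of 1 Mb, 8 TE families x 25 copies, 300
#' genes, 150-200 peaks, 300 footprint sites) keep a full run to roughly a
#' minute while leaving every planted effect comfortably detectable.
#'
#' @param seed Integer seed controlling all randomness.
#' @param config A [pipeline_config()]; thresholds and replicate counts for
#'   the analysis stages.
#' @param n_genes,n_families,copies_per_family,n_peaks Problem sizes.
#' @param up_fold_change Linear fold change planted in upregulated
#'   families, copies and genes.
#' @param peak_enrichment_factor Placement enrichment of peaks near the
#'   planted family.
#' @param footprint_depths Named vector of motif protection depths per
#'   condition, `c(ctrl = ..., treat = ...)`.
#' @param n_shuffles,n_resamples Override the config's null sizes (handy
#'   for quick runs).
#' @return Object of class `te_pipeline_run`: a list with the generated
#'   data (`genome`, `te`, `genes`, `truth`), the fitted stages
#'   (`family_fit`, `copy_fit`, `gene_fit`, `peak_fit`, `enrichment`,
#'   `crossed`, `proximity`, `fos_fit`) and the derived sets
#'   (`de_families`, `de_copies`, `de_genes`, `peaks`).
#' @export
run_synthetic_pipeline <- function(seed = 1L,
                                   config = pipeline_config(rng_seed = seed),
                                   n_genes = 300L,
                                   n_families = 8L,
                                   copies_per_family = 25L,
                                   n_peaks = 200L,
                                   up_fold_change = 4,
                                   peak_enrichment_factor = 5,
                                   footprint_depths = c(ctrl = 0.2, treat = 0.7),
                                   n_shuffles = config$n_shuffles_atac,
                                   n_resamples = config$n_resamples_proximity) {
  seed <- as.integer(seed)
  # --- generate ------------------------------------------------------------
  genome <- simulate_genome(2, 1e6, 0.05, seed = seed)
  te <- simulate_te_annotation(genome, n_families, copies_per_family,
                               c(100L, 500L), seed = seed + 11L)
  families <- unique(te$family)
  up_families <- families[1:2]
  enriched_family <- families[1]
  up_copies <- te$copy_id[te$family %in% up_families]

  gene_sim <- simulate_gene_annotation(
    genome, n_genes, te, frac_proximal = 0.3,
    window = config$proximity_window,
    copies = up_copies, seed = seed + 23L
  )
  genes <- gene_sim$genes

  # DEGs: 60% of the TE-coupled genes plus a background of uncoupled ones
  coupled <- unique(gene_sim$truth$gene_id)
  n_coupled_de <- ceiling(0.6 * length(coupled))
  other <- setdiff(genes$gene_id, coupled)
  de_genes_truth <- withr::with_seed(seed + 31L, {
    c(coupled[seq_len(n_coupled_de)],
      other[sample.int(length(other), min(30L, length(other)))])
  })

  # genes and TE families share one matrix so they are normalized together
  joint_features <- bind_rows(
    tibble(feature_id = genes$gene_id, kind = "gene"),
    tibble(feature_id = families, kind = "te_family")
  )
  joint_fc <- c(
    setNames(rep(up_fold_change, length(de_genes_truth)), de_genes_truth),
    setNames(rep(up_fold_change, length(up_families)), up_families)
  )
  joint_sim <- simulate_counts(joint_features, n_reps = 3L, base_mean = 500,
                               dispersion = 0.05, fold_changes = joint_fc,
                               seed = seed + 41L)

  copy_features <- tibble(feature_id = te$copy_id, kind = "te_copy")
  copy_sim <- simulate_counts(copy_features, n_reps = 3L, base_mean = 200,
                              dispersion = 0.05,
                              fold_changes = setNames(
                                rep(up_fold_change, length(up_copies)), up_copies),
                              seed = seed + 43L)

  # --- differential expression --------------------------------------------
  joint_fit <- nb_test(joint_sim$counts, joint_sim$design,
                       fc_cutoff = config$fc_cutoff, alpha = config$alpha)
  joint_res <- tidy(joint_fit)
  fam_cls <- classify(filter(joint_res, .data$kind == "te_family"),
                      config$fc_cutoff, config$alpha)
  gene_cls <- classify(filter(joint_res, .data$kind == "gene"),
                       config$fc_cutoff, config$alpha)

  copy_fit <- nb_test(copy_sim$counts, copy_sim$design,
                      fc_cutoff = config$fc_cutoff, alpha = config$alpha,
                      pairwise_norm = TRUE)
  copy_cls <- classify(copy_fit, config$fc_cutoff, config$alpha)

  # --- peaks ---------------------------------------------------------------
  peaks_0 <- simulate_peaks(genome, te, character(), 1,
                            n_peaks = as.integer(round(0.75 * n_peaks)),
                            peak_len = 400L, pad = config$te_pad,
                            seed = seed + 53L)$peaks
  peaks_t_sim <- simulate_peaks(genome, te, enriched_family,
                                peak_enrichment_factor, n_peaks = n_peaks,
                                peak_len = 400L, pad = config$te_pad,
                                seed = seed + 59L)
  peaks_t <- peaks_t_sim$peaks
  peaks_0 <- filter_min_length(peaks_0, config$min_peak_len)
  peaks_t <- filter_min_length(peaks_t, config$min_peak_len)
  consensus <- merge_peaks(peaks_t, peaks_0)
  sets <- gained_lost(consensus, peaks_t, peaks_0)

  # per-peak accessibility counts: gained peaks open up, lost peaks close
  peak_fc <- c(setNames(rep(6, nrow(sets$gained)), sets$gained$name),
               setNames(rep(1 / 6, nrow(sets$lost)), sets$lost$name))
  peak_sim <- simulate_counts(
    tibble(feature_id = consensus$name, kind = "peak"),
    n_reps = 3L, base_mean = 100, dispersion = 0.05,
    fold_changes = peak_fc, seed = seed + 61L
  )
  peak_fit <- peak_count_significance(peak_sim$counts, peak_sim$design,
                                      fc_cutoff = config$fc_cutoff,
                                      alpha = config$alpha)

  # --- TE-family enrichment in gained accessibility ------------------------
  enrichment <- te_family_enrichment(
    sets$gained, te, genome, pad = config$te_pad,
    n_shuffles = n_shuffles, alpha = config$alpha, seed = seed + 67L
  )
  crossed <- cross_with_de(enrichment, fam_cls)

  # --- TE-copy/gene proximity ----------------------------------------------
  te_up_tbl <- filter(te, .data$copy_id %in% copy_cls$up)
  proximity <- te_gene_proximity(
    te_up_tbl, genes, degs = gene_cls$up,
    universe = genes$gene_id, window = config$proximity_window,
    n_resamples = n_resamples, seed = seed + 71L
  )

  # --- footprinting --------------------------------------------------------
  fp <- purrr::imap(footprint_depths, function(depth, cond) {
    simulate_insertion_profiles(300L, flank = 100L, motif_len = 15L,
                                background_rate = 0.5,
                                footprint_depth = depth,
                                seed = seed + 79L + match(cond, names(footprint_depths)))
  })
  fos_by_cond <- purrr::map(fp, fos)
  fos_fit <- compare_fos(fos_by_cond[[2]], fos_by_cond[[1]])

  truth <- list(
    up_families = up_families,
    up_copies = up_copies,
    de_genes = de_genes_truth,
    enriched_families = enriched_family,
    proximal_pairs = gene_sim$truth,
    footprint_depth_by_condition = footprint_depths
  )
  structure(
    list(
      genome = genome, te = te, genes = genes, truth = truth,
      family_fit = joint_fit, copy_fit = copy_fit,
      de_families = fam_cls, de_copies = copy_cls, de_genes = gene_cls,
      peaks = list(t0 = peaks_0, t = peaks_t, consensus = consensus,
                   gained = sets$gained, lost = sets$lost,
                   common = sets$common),
      peak_fit = peak_fit,
      enrichment = enrichment, crossed = crossed,
      proximity = proximity,
      footprints = fp, fos_fit = fos_fit,
      config = config, seed = seed
    ),
    class = "te_pipeline_run"
  )
}

#' @export
print.te_pipeline_run <- function(x, ...) {
  cat("<te_pipeline_run> seed ", x$seed, "\n", sep = "")
  cat("  families up: ", paste(x$de_families$up, collapse = ", "), "\n", sep = "")
  cat("  copies up: ", length(x$de_copies$up), "/",
      length(x$truth$up_copies), " planted\n", sep = "")
  cat("  peaks: ", nrow(x$peaks$gained), " gained, ", nrow(x$peaks$lost),
      " lost, ", nrow(x$peaks$common), " common\n", sep = "")
  flagged <- x$crossed$family[x$crossed$flagged]
  cat("  accessibility-enriched & DE: ",
      if (length(flagged)) paste(flagged, collapse = ", ") else "none", "\n",
      sep = "")
  cat("  proximity p_binom = ",
      signif(x$proximity$summary$p_binomial_vs_null, 3), "\n", sep = "")
  cat("  footprint mean log2 FOS diff = ",
      signif(x$fos_fit$summary$mean_log2_diff, 3), " (p = ",
      signif(x$fos_fit$summary$p_value, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname run_synthetic_pipeline
#' @param x A `te_pipeline_run` object.
#' @param ... Unused.
#' @method glance te_pipeline_run
#' @export
glance.te_pipeline_run <- function(x, ...) {
  planted_up <- x$truth$up_families
  tibble(
    family_recovery = mean(planted_up %in% x$de_families$up),
    copy_recovery = mean(x$truth$up_copies %in% x$de_copies$up),
    gene_recovery = mean(x$truth$de_genes %in%
                           c(x$de_genes$up, x$de_genes$down)),
    enriched_family_flagged =
      all(x$truth$enriched_families %in% x$crossed$family[x$crossed$flagged]),
    n_gained = nrow(x$peaks$gained),
    n_lost = nrow(x$peaks$lost),
    n_common = nrow(x$peaks$common),
    proximity_p_hyper = x$proximity$summary$p_hypergeom,
    proximity_p_binom = x$proximity$summary$p_binomial_vs_null,
    fos_mean_log2_diff = x$fos_fit$summary$mean_log2_diff,
    fos_p = x$fos_fit$summary$p_value
  )
}
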