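# Unsigned distance from a TE copy interval [start, end) to a TSS point:
# 0 when the TSS lies inside the copy, else base-pair gap to the nearest
# copy base.
copy_tss_distance <- function(start, end, tss) {
  dplyr::case_when(
    tss >= start & tss < end ~ 0L,
    tss < start ~ start - tss,
    TRUE ~ tss - (end - 1L)
  )
}

#' Assign each TE copy to its closest gene TSS
#'
#' For every copy the gene whose TSS minimizes the unsigned distance to the
#' copy interval (0 when the copy spans the TSS). Ties are broken by gene
#' order after sorting on (`chrom`, `start`, `gene_id`). The reported
#' distance is signed relative to the TE copy's orientation: positive when
#' the TSS lies downstream of the copy (3' side on the copy's strand),
#' negative upstream.
#'
#' @param te_copies TE copy tibble (needs `copy_id`, `chrom`, `start`,
#'   `end`, optionally `strand`; unstranded copies use `+`).
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @return Tibble (`copy_id`, `gene_id`, `distance`); copies on chromosomes
#'   without genes get `gene_id = NA` and are counted in the
#'   `n_unassigned` attribute.
#' @export
closest_gene <- function(te_copies, genes) {
  if (nrow(genes) == 0) abort("gene annotation is empty")
  genes <- arrange(genes, .data$chrom, .data$start, .data$gene_id)
  strand <- if ("strand" %in% names(te_copies)) te_copies$strand else
    rep("+", nrow(te_copies))
  out <- purrr::map_dfr(seq_len(nrow(te_copies)), function(i) {
    g <- genes[genes$chrom == te_copies$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      return(tibble(copy_id = te_copies$copy_id[i], gene_id = NA_character_,
                    distance = NA_integer_))
    }
    d <- copy_tss_distance(te_copies$start[i], te_copies$end[i], g$tss)
    k <- which.min(d)  # first minimum = tie by sort order
    signed <- d[k]
    if (signed > 0) {
      downstream <- g$tss[k] >= te_copies$end[i]
      if (strand[i] == "-") downstream <- !downstream
      signed <- if (downstream) signed else -signed
    }
    tibble(copy_id = te_copies$copy_id[i], gene_id = g$gene_id[k],
           distance = as.integer(signed))
  })
  attr(out, "n_unassigned") <- sum(is.na(out$gene_id))
  if (attr(out, "n_unassigned") > 0) {
    warn(sprintf("%d cop(ies) on chromosomes without genes left unassigned",
                 attr(out, "n_unassigned")))
  }
  out
}

#' Genes with a TSS within a window of any TE copy
#'
#' A gene is proximal when its TSS lies within `window` bp of any of the
#' supplied copies, i.e. the copy overlaps `[TSS - window, TSS + window]`;
#' the boundary is inclusive, so a distance of exactly `window` counts.
#'
#' @param te_copies TE copy tibble (typically the upregulated copies).
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @param window Half-width in bp (default 30 kb).
#' @return Character vector of proximal `gene_id`s.
#' @export
proximal_genes <- function(te_copies, genes, window = 30000L) {
  stopifnot(window > 0)
  if (nrow(genes) == 0 || nrow(te_copies) == 0) return(character())
  window <- as.integer(window)
  tss_win <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - window),
    end = genes$tss + window + 1L  # half-open; +window inclusive
  )
  hits <- overlap_pairs(tss_win, te_copies)
  unique(genes$gene_id[unique(hits$query_idx)])
}

#' Hypergeometric and Fisher tests for DEG overlap with proximal genes
#'
#' Tests whether deregulated genes (`degs`) overlap the TE-proximal gene
#' set more than expected from the gene universe: upper-tail
#' hypergeometric `P(X >= k)` with `N = |universe|`, `K = |proximal|`,
#' `n = |degs|`, plus the two-sided Fisher exact test on the same 2x2
#' table.
#'
#' @param proximal Character vector of proximal gene ids.
#' @param degs Character vector of deregulated gene ids.
#' @param universe Character vector of all tested gene ids; `proximal` and
#'   `degs` must be subsets.
#' @return One-row tibble: `overlap`, `n_proximal`, `n_degs`,
#'   `universe_size`, `p_hypergeom`, `p_fisher`.
#' @export
observed_overlap_test <- function(proximal, degs, universe) {
  if (length(universe) == 0) abort("empty gene universe")
  proximal <- unique(proximal); degs <- unique(degs); universe <- unique(universe)
  if (!all(proximal %in% universe) || !all(degs %in% universe)) {
    abort("proximal and degs must be subsets of the universe")
  }
  k <- length(intersect(proximal, degs))
  N <- length(universe); K <- length(proximal); n <- length(degs)
  p_hyper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2)
  p_fisher <- fisher.test(tab)$p.value
  tibble(overlap = k, n_proximal = K, n_degs = n, universe_size = N,
         p_hypergeom = p_hyper, p_fisher = p_fisher)
}

#' Resampled background for the proximity overlap
#'
#' Draws `degs_size` genes without replacement from the background pool
#' `remaining` (by default the universe minus the observed DEGs) and counts
#' how many fall in the proximal set, repeated `n_resamples` times. The
#' mean of these null overlaps is the expected overlap under no
#' association.
#'
#' @param degs_size Number of genes per resample.
#' @param remaining Character vector of background gene ids.
#' @param proximal Character vector of proximal gene ids.
#' @param n_resamples Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @return List with `null_overlaps` (integer vector of length
#'   `n_resamples`) and `null_mean`.
#' @export
resampled_background <- function(degs_size, remaining, proximal,
                                 n_resamples = 10000L, seed = 1L) {
  remaining <- unique(remaining)
  if (degs_size > length(remaining)) {
    abort("degs_size exceeds the background pool")
  }
  stopifnot(n_resamples >= 1)
  is_prox <- remaining %in% proximal
  null_overlaps <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      sum(is_prox[sample.int(length(remaining), degs_size)])
    }, integer(1))
  })
  list(null_overlaps = null_overlaps, null_mean = mean(null_overlaps))
}

#' Binomial test of the observed overlap against the resampled expectation
#'
#' Upper-tail exact binomial `P(X >= observed)` with `n = degs_size` trials
#' and success probability `null_mean / degs_size` — the expected overlap
#' rate estimated from the resampled background.
#'
#' @param observed Observed overlap count.
#' @param degs_size Number of DEGs (trials).
#' @param null_mean Mean overlap across resamples.
#' @return P-value. A degenerate null (`null_mean = 0` with `observed > 0`)
#'   returns 0 with a warning.
#' @export
binomial_vs_null <- function(observed, degs_size, null_mean) {
  stopifnot(observed >= 0, degs_size >= observed)
  if (null_mean < 0 || null_mean > degs_size) {
    abort("null_mean must lie in [0, degs_size]")
  }
  if (null_mean == 0) {
    if (observed > 0) {
      warn("degenerate null: expected overlap is 0 but observed > 0")
      return(0)
    }
    return(1)
  }
  pbinom(observed - 1, degs_size, null_mean / degs_size, lower.tail = FALSE)
}

#' TE-copy/gene proximity enrichment test
#'
#' The full proximity analysis: finds genes whose TSS lies within `window`
#' bp of an upregulated TE copy, tests their overlap with the deregulated
#' gene set by hypergeometric and Fisher tests, and compares the observed
#' overlap with a resampled-gene background (genes drawn from the
#' non-deregulated remainder by default) via an exact binomial test on the
#' resampled expectation.
#'
#' @param te_up Tibble of upregulated TE copies.
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`).
#' @param degs Character vector of deregulated gene ids.
#' @param universe Character vector of all tested genes (defaults to
#'   `genes$gene_id`).
#' @param window Proximity window half-width in bp (default 30 kb).
#' @param n_resamples Number of background resamples (default 10,000).
#' @param background `"non-deg"` samples from the universe minus the DEGs;
#'   `"all"` samples from the full universe.
#' @param seed Integer seed.
#' @return Object of class `te_proximity`; [tidy()] gives the one-row
#'   summary, `$null_overlaps` holds the full null vector.
#' @export
te_gene_proximity <- function(te_up, genes, degs, universe = NULL,
                              window = 30000L, n_resamples = 10000L,
                              background = c("non-deg", "all"), seed = 1L) {
  background <- match.arg(background)
  universe <- unique(universe %||% genes$gene_id)
  degs <- unique(intersect(degs, universe))
  prox <- intersect(proximal_genes(te_up, genes, window = window), universe)

  obs <- observed_overlap_test(prox, degs, universe)
  pool <- if (background == "non-deg") setdiff(universe, degs) else universe
  bg <- resampled_background(length(degs), pool, prox,
                             n_resamples = n_resamples, seed = seed)
  p_binom <- binomial_vs_null(obs$overlap, length(degs), bg$null_mean)

  structure(
    list(
      summary = bind_cols(obs, tibble(
        null_mean_overlap = bg$null_mean,
        p_binomial_vs_null = p_binom,
        n_resamples = as.integer(n_resamples),
        window = as.integer(window),
        background = background,
        n_te_copies = nrow(te_up)
      )),
      proximal = prox,
      null_overlaps = bg$null_overlaps
    ),
    class = "te_proximity"
  )
}

#' @export
print.te_proximity <- function(x, ...) {
  s <- x$summary
  cat("<te_proximity> ", s$overlap, "/", s$n_degs,
      " deregulated genes proximal (", s$n_proximal, " proximal of ",
      s$universe_size, "); null mean ", round(s$null_mean_overlap, 2),
      "; p_hyper = ", signif(s$p_hypergeom, 3),
      ", p_binom = ", signif(s$p_binomial_vs_null, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname te_gene_proximity
#' @param x A `te_proximity` object.
#' @param ... Unused.
#' @method tidy te_proximity
#' @export
tidy.te_proximity <- function(x, ...) x$summary

#' @rdname te_gene_proximity
#' @method glance te_proximity
#' @export
glance.te_proximity <- function(x, ...) x$summary

#' Null-overlap histogram with the observed overlap marked
#'
#' @param object A `te_proximity` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot te_proximity
#' @export
autoplot.te_proximity <- function(object, ...) {
  d <- tibble(null_overlap = object$null_overlaps)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null_overlap)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$summary$overlap,
                        colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(x = "resampled overlap with proximal genes", y = "resamples")
}
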