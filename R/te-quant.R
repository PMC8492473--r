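#' Count uniquely mapped reads per TE copy
#'
#' Copy-level quantification uses only reads with a single reported
#' alignment (`n_hits == 1`), the analogue of extracting uniquely mapped
#' reads by MAPQ filtering. A unique read increments a copy when its
#' interval overlaps the copy by at least 1 bp; a read overlapping several
#' copies is assigned to the copy with the largest overlap, ties broken by
#' the lexicographically smallest `copy_id`. Counting is unstranded.
#'
#' @param reads Tibble of alignment records with columns `read_id`, `chrom`,
#'   `start`, `end`, `n_hits` (one row per candidate placement).
#' @param te_annotation TE copy tibble (see [simulate_te_annotation()]).
#' @param genome Optional [genome_model()]; reads on chromosomes absent from
#'   it are skipped with a warning and tallied in the QC attribute.
#' @param sample Column name for the single output sample.
#' @return Tibble (`feature_id`, `kind = "te_copy"`, one count column), one
#'   row per annotated copy, with a `qc` attribute listing skipped and
#'   unassigned read tallies.
#' @export
count_te_copies <- function(reads, te_annotation, genome = NULL,
                            sample = "sample1") {
  validate_intervals(reads, what = "reads")
  qc <- list(n_unknown_chrom = 0L, n_multi_excluded = 0L, n_outside_te = 0L)

  if (!is.null(genome)) {
    known <- reads$chrom %in% genome$chrom_sizes$chrom
    qc$n_unknown_chrom <- length(unique(reads$read_id[!known]))
    if (qc$n_unknown_chrom > 0) {
      warn(sprintf("skipping %d read(s) on chromosomes absent from the genome",
                   qc$n_unknown_chrom))
      reads <- reads[known, , drop = FALSE]
    }
  }
  uni <- filter(reads, .data$n_hits == 1)
  qc$n_multi_excluded <- dplyr::n_distinct(reads$read_id) - nrow(uni)

  counts <- rep(0L, nrow(te_annotation))
  names(counts) <- te_annotation$copy_id
  if (nrow(uni) > 0 && nrow(te_annotation) > 0) {
    pairs <- overlap_pairs(uni, te_annotation)
    if (nrow(pairs) > 0) {
      pairs$width <- overlap_widths(uni, te_annotation, pairs)
      pairs$copy_id <- te_annotation$copy_id[pairs$subject_idx]
      assigned <- pairs %>%
        arrange(.data$query_idx, dplyr::desc(.data$width), .data$copy_id) %>%
        distinct(.data$query_idx, .keep_all = TRUE)
      tab <- table(assigned$copy_id)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
      qc$n_outside_te <- nrow(uni) - nrow(assigned)
    } else {
      qc$n_outside_te <- nrow(uni)
    }
  } else {
    qc$n_outside_te <- nrow(uni)
  }

  out <- tibble(
    feature_id = te_annotation$copy_id,
    kind = "te_copy",
    !!sample := unname(counts)
  )
  attr(out, "qc") <- qc
  out
}

#' Count reads per TE family with multi-mapper redistribution
#'
#' Family-level quantification keeps multi-mapping reads, the bulk of the
#' signal for young TE families. Every candidate placement of a read is
#' matched to the family whose copy it overlaps (placements overlapping no
#' copy feed an implicit non-TE sink). A unique read contributes weight 1
#' to its family; a multi-mapper distributes weight across its candidate
#' placements either uniformly (`mode = "uniform"`) or by expectation-
#' maximization (`mode = "em"`), which iteratively reweights placements in
#' proportion to current family abundance so that families with more unique
#' support absorb more of the ambiguous mass. Total assigned weight equals
#' the number of reads (mass conservation, including the sink).
#'
#' @inheritParams count_te_copies
#' @param mode `"uniform"` or `"em"`.
#' @param em_iters Maximum EM iterations (default 100); iteration also stops
#'   when the largest change in any family weight falls below `tol`.
#' @param tol Convergence tolerance on family-weight change.
#' @return Tibble (`feature_id`, `kind = "te_family"`, one count column per
#'   sample; fractional values allowed), one row per family, with a `qc`
#'   attribute (`sink_mass`, skipped-read tallies) and, for EM, an `em`
#'   attribute with the log-likelihood trace.
#' @export
count_te_families <- function(reads, te_annotation, mode = c("uniform", "em"),
                              em_iters = 100L, tol = 1e-8, genome = NULL,
                              sample = "sample1") {
  mode <- match.arg(mode)
  stopifnot(em_iters >= 1)
  validate_intervals(reads, what = "reads")
  qc <- list(n_unknown_chrom = 0L, sink_mass = 0)

  if (!is.null(genome)) {
    known <- reads$chrom %in% genome$chrom_sizes$chrom
    qc$n_unknown_chrom <- length(unique(reads$read_id[!known]))
    if (qc$n_unknown_chrom > 0) {
      warn(sprintf("skipping %d read(s) on chromosomes absent from the genome",
                   qc$n_unknown_chrom))
      reads <- reads[known, , drop = FALSE]
    }
  }

  families <- unique(te_annotation$family)
  sink_label <- ".non_TE"
  comp_levels <- c(families, sink_label)

  # map every placement to a component (family or sink); a placement
  # overlapping copies of k families counts once per family
  placement_comp <- if (nrow(reads) > 0 && nrow(te_annotation) > 0) {
    pairs <- overlap_pairs(reads, te_annotation)
    hit <- tibble(
      row = pairs$query_idx,
      comp = te_annotation$family[pairs$subject_idx]
    ) %>% distinct()
    no_hit <- setdiff(seq_len(nrow(reads)), unique(hit$row))
    bind_rows(hit, tibble(row = no_hit, comp = sink_label))
  } else {
    tibble(row = seq_len(nrow(reads)), comp = sink_label)
  }
  placement_comp$read_id <- reads$read_id[placement_comp$row]

  # per-read component multiplicities m_rf
  m <- placement_comp %>% count(.data$read_id, .data$comp, name = "mult")
  reads_n <- dplyr::n_distinct(reads$read_id)

  out_counts <- setNames(rep(0, length(comp_levels)), comp_levels)
  em_info <- NULL
  if (nrow(m) > 0) {
    m <- m %>%
      group_by(.data$read_id) %>%
      mutate(total_mult = sum(.data$mult)) %>%
      ungroup()
    if (mode == "uniform") {
      w <- m$mult / m$total_mult
      agg <- tapply(w, m$comp, sum)
      out_counts[names(agg)] <- as.numeric(agg)
    } else {
      res <- em_family_weights(m, comp_levels, em_iters, tol)
      out_counts <- res$counts
      em_info <- res[c("log_lik", "n_iter", "converged")]
    }
  }

  qc$sink_mass <- unname(out_counts[sink_label])
  out <- tibble(
    feature_id = families,
    kind = "te_family",
    !!sample := unname(out_counts[families])
  )
  attr(out, "qc") <- qc
  attr(out, "n_reads_assigned") <- reads_n
  if (!is.null(em_info)) attr(out, "em") <- em_info
  out
}

# EM for the multinomial mixture P(read r | pi) = sum_f pi_f * m_rf / M_r.
# Responsibilities w_rf ∝ pi_f * m_rf; pi updated as mean responsibility.
em_family_weights <- function(m, comp_levels, em_iters, tol) {
  comp_idx <- match(m$comp, comp_levels)
  read_idx <- match(m$read_id, unique(m$read_id))
  n_reads <- max(read_idx)
  k <- length(comp_levels)

  pi <- rep(1 / k, k)
  log_lik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    score <- pi[comp_idx] * m$mult
    denom <- tapply(score, read_idx, sum)[as.character(read_idx)]
    w <- score / as.numeric(denom)
    mass <- tapply(w, comp_idx, sum)
    new_counts <- setNames(rep(0, k), comp_levels)
    new_counts[as.integer(names(mass))] <- as.numeric(mass)
    new_pi <- new_counts / n_reads
    log_lik <- c(log_lik, sum(log(tapply(pi[comp_idx] * m$mult, read_idx, sum))))
    delta <- max(abs(new_pi - pi))
    pi <- new_pi
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= em_iters) break
  }
  list(counts = pi * n_reads, log_lik = log_lik, n_iter = iter,
       converged = converged)
}
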