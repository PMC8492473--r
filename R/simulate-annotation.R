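te_superfamilies <- c("ERV1", "ERVK", "ERVL", "L1", "B1")
te_classes <- c(ERV1 = "LTR", ERVK = "LTR", ERVL = "LTR", L1 = "LINE", B1 = "SINE")

#' Simulate a transposable-element annotation
#'
#' Places `n_families * copies_per_family` TE copies uniformly at random in
#' the genome, mutually disjoint and disjoint from the excluded regions,
#' mimicking a RepeatMasker-style annotation. Family labels follow the
#' `name:superfamily:class` convention (e.g. `"SimTE1:ERV1:LTR"`), the
#' format in which TE families are reported throughout the pipeline.
#'
#' @param genome A [genome_model()].
#' @param n_families Number of TE families.
#' @param copies_per_family Copies per family.
#' @param copy_len Length range in bp, `c(min, max)` (a single value fixes
#'   the length).
#' @param seed Integer seed.
#' @return Tibble with columns `copy_id`, `family` (full label),
#'   `superfamily`, `te_class`, `chrom`, `start`, `end`, `strand`.
#' @examples
#' gm <- simulate_genome(1, 1e6, 0, seed = 1)
#' te <- simulate_te_annotation(gm, 5, 10, c(100, 500), seed = 3)
#' @export
simulate_te_annotation <- function(genome, n_families, copies_per_family,
                                   copy_len = c(100L, 500L), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), n_families >= 0, copies_per_family >= 1)
  if (length(copy_len) == 1) copy_len <- rep(copy_len, 2)
  stopifnot(copy_len[1] >= 1, copy_len[2] >= copy_len[1])
  empty <- tibble(
    copy_id = character(), family = character(), superfamily = character(),
    te_class = character(), chrom = character(), start = integer(),
    end = integer(), strand = character()
  )
  if (n_families == 0) return(empty)

  sf <- te_superfamilies[(seq_len(n_families) - 1L) %% length(te_superfamilies) + 1L]
  fam_labels <- paste0("SimTE", seq_len(n_families), ":", sf, ":", te_classes[sf])
  n_total <- n_families * copies_per_family

  withr::with_seed(seed, {
    lens <- copy_len[1] +
      sample.int(copy_len[2] - copy_len[1] + 1L, n_total, replace = TRUE) - 1L
    if (sum(lens) >= sum(genome$chrom_sizes$length) - covered_bp(genome$excluded)) {
      abort("total TE bp exceeds available genome space")
    }
    free <- gaps_intervals(genome$excluded, genome$chrom_sizes)
    rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      pos <- sample_start_uniform(free, lens[i])
      if (is.null(pos)) {
        abort(sprintf("TE packing infeasible at copy %d of %d", i, n_total))
      }
      rows[[i]] <- tibble(chrom = pos$chrom, start = pos$start,
                          end = pos$start + lens[i])
      free <- subtract_intervals(free, rows[[i]])
    }
    copies <- bind_rows(rows)
    copies$strand <- sample(c("+", "-"), n_total, replace = TRUE)
    copies$family <- rep(fam_labels, each = copies_per_family)
    copies$superfamily <- rep(sf, each = copies_per_family)
    copies$te_class <- rep(unname(te_classes[sf]), each = copies_per_family)
    copies$copy_id <- paste0(
      sub(":.*", "", copies$family), "_c",
      rep(seq_len(copies_per_family), times = n_families)
    )
    select(copies, "copy_id", "family", "superfamily", "te_class",
           "chrom", "start", "end", "strand")
  })
}

#' Simulate a gene annotation with controlled TE proximity
#'
#' Places gene transcription start sites (TSS) so that approximately
#' `frac_proximal` of genes fall within `window` bp of a designated TE copy
#' (the coupling recorded as ground-truth pairs) and the remainder fall
#' strictly farther than `window` from every designated copy. Gene bodies
#' extend 1-10 kb from the TSS in the strand direction, clipped to the
#' chromosome.
#'
#' @param genome A [genome_model()].
#' @param n_genes Number of genes.
#' @param te_annotation TE copy tibble as from [simulate_te_annotation()].
#' @param frac_proximal Fraction of genes to couple to TE copies, in `[0, 1]`.
#' @param window Proximity window half-width in bp (default 30 kb).
#' @param copies Optional subset of `copy_id`s to designate; defaults to all.
#' @param seed Integer seed.
#' @return List with `genes` (tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`) and `truth` (tibble of designated
#'   `copy_id`/`gene_id` pairs).
#' @export
simulate_gene_annotation <- function(genome, n_genes, te_annotation,
                                     frac_proximal = 0, window = 30000L,
                                     copies = NULL, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), n_genes >= 0,
            frac_proximal >= 0, frac_proximal <= 1)
  window <- as.integer(window)
  if (any(window >= genome$chrom_sizes$length)) {
    abort("proximity window is at least as large as a chromosome")
  }
  designated <- if (is.null(copies)) te_annotation else
    filter(te_annotation, .data$copy_id %in% copies)
  n_prox <- round(frac_proximal * n_genes)
  if (n_prox > 0 && nrow(designated) == 0) {
    abort("no designated TE copies to place proximal genes near")
  }

  # TSS positions > window away from every designated copy live here
  zone <- tibble(
    chrom = designated$chrom,
    start = pmax(0L, designated$start - window),
    end = pmin(designated$end + window,
               setNames(genome$chrom_sizes$length,
                        genome$chrom_sizes$chrom)[designated$chrom])
  )
  far_space <- gaps_intervals(zone, genome$chrom_sizes)
  if (n_prox < n_genes && sum(far_space$end - far_space$start) == 0) {
    abort("no genomic space farther than `window` from the designated copies")
  }

  withr::with_seed(seed, {
    rows <- vector("list", n_genes)
    pair_copy <- character(n_genes)
    for (i in seq_len(n_genes)) {
      if (i <= n_prox) {
        k <- sample.int(nrow(designated), 1L)
        chrom <- designated$chrom[k]
        chrom_len <- genome$chrom_sizes$length[genome$chrom_sizes$chrom == chrom]
        lo <- max(0L, designated$start[k] - window)
        hi <- min(chrom_len - 1L, designated$end[k] - 1L + window)
        tss <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        pair_copy[i] <- designated$copy_id[k]
      } else {
        pos <- sample_start_uniform(far_space, 1L)
        chrom <- pos$chrom
        tss <- pos$start
      }
      rows[[i]] <- tibble(chrom = chrom, tss = as.integer(tss))
    }
    genes <- bind_rows(rows)
    genes$gene_id <- sprintf("gene%04d", seq_len(n_genes))
    genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    body_len <- sample(1000:10000, max(n_genes, 1), replace = TRUE)[seq_len(n_genes)]
    chrom_len <- setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
    genes <- mutate(genes,
      start = if_else(.data$strand == "+", .data$tss,
                      pmax(0L, .data$tss + 1L - body_len)),
      end = if_else(.data$strand == "+",
                    pmin(as.integer(chrom_len[.data$chrom]), .data$tss + body_len),
                    .data$tss + 1L)
    )
    truth <- tibble(copy_id = pair_copy[seq_len(n_prox)],
                    gene_id = genes$gene_id[seq_len(n_prox)])
    list(
      genes = select(genes, "gene_id", "chrom", "start", "end", "strand", "tss"),
      truth = truth
    )
  })
}
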