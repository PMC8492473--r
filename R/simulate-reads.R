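#' Simulate simplified alignment records over TE copies
#'
#' Generates the alignment-record table consumed by [count_te_copies()] and
#' [count_te_families()]: per-copy uniquely mapped reads (one candidate
#' placement, `n_hits = 1`) plus multi-mapping reads whose candidate
#' placements fall in several copies of the same or different families —
#' the ambiguity structure that family-level counting must resolve. Read
#' placements land fully inside their source copy whenever the copy is
#' longer than the read; the number of unique reads per copy is Poisson
#' with mean `unique_rate`, and `n_multi` multi-mappers each draw
#' `hits_per_multi` distinct target copies (weighted toward the same
#' family as the first target with probability `same_family_bias`).
#'
#' @param te_annotation TE copy tibble.
#' @param unique_rate Mean unique reads per copy.
#' @param n_multi Number of multi-mapping reads.
#' @param hits_per_multi Candidate placements per multi-mapper (>= 2).
#' @param read_len Read length in bp.
#' @param same_family_bias Probability that each extra placement of a
#'   multi-mapper stays within the first target's family.
#' @param seed Integer seed.
#' @return Tibble (`read_id`, `chrom`, `start`, `end`, `n_hits`,
#'   `hit_index`), one row per candidate placement, plus a `truth`
#'   attribute with the per-copy unique-read counts.
#' @export
simulate_te_reads <- function(te_annotation, unique_rate = 5, n_multi = 0L,
                              hits_per_multi = 2L, read_len = 50L,
                              same_family_bias = 0.8, seed = 1L) {
  stopifnot(nrow(te_annotation) > 0, unique_rate >= 0, n_multi >= 0,
            hits_per_multi >= 2, read_len >= 1)
  te <- te_annotation
  withr::with_seed(seed, {
    place_in_copy <- function(copy_idx) {
      s <- te$start[copy_idx]; e <- te$end[copy_idx]
      span <- max(e - s - read_len, 0L)
      st <- s + if (span > 0) sample.int(span + 1L, 1L) - 1L else 0L
      tibble(chrom = te$chrom[copy_idx], start = as.integer(st),
             end = as.integer(st + min(read_len, e - s)))
    }

    n_uni <- rpois(nrow(te), unique_rate)
    uni <- purrr::map_dfr(which(n_uni > 0), function(i) {
      bind_cols(
        tibble(copy_idx = rep(i, n_uni[i])),
        purrr::map_dfr(seq_len(n_uni[i]), function(j) place_in_copy(i))
      )
    })
    if (nrow(uni) > 0) {
      uni <- mutate(uni,
                    read_id = sprintf("uread%05d", row_number()),
                    n_hits = 1L, hit_index = 1L)
    }

    multi <- purrr::map_dfr(seq_len(n_multi), function(r) {
      first <- sample.int(nrow(te), 1L)
      fam <- te$family[first]
      targets <- first
      for (k in seq_len(hits_per_multi - 1L)) {
        pool <- if (runif(1) < same_family_bias) {
          setdiff(which(te$family == fam), targets)
        } else {
          setdiff(seq_len(nrow(te)), targets)
        }
        if (!length(pool)) pool <- setdiff(seq_len(nrow(te)), targets)
        if (!length(pool)) break
        targets <- c(targets, pool[sample.int(length(pool), 1L)])
      }
      bind_cols(
        tibble(copy_idx = targets,
               read_id = sprintf("mread%05d", r),
               n_hits = length(targets),
               hit_index = seq_along(targets)),
        purrr::map_dfr(targets, place_in_copy)
      )
    })

    reads <- bind_rows(uni, multi)
    truth <- if (nrow(uni) > 0) {
      tab <- table(te$copy_id[uni$copy_idx])
      tibble(copy_id = names(tab), unique_reads = as.integer(tab))
    } else {
      tibble(copy_id = character(), unique_reads = integer())
    }
    out <- select(reads, "read_id", "chrom", "start", "end",
                  "n_hits", "hit_index")
    attr(out, "truth") <- truth
    out
  })
}
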