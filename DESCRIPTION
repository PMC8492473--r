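Package: teresurge
Title: Transposable-Element Reactivation Analysis for Bulk RNA-seq and ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for quantifying transposable-element
    (TE) expression at family and copy level from multi-mapping-aware
    alignment records, classifying deregulated features with a negative
    binomial Wald test, constructing gained/lost chromatin-accessibility peak
    sets, testing TE-family enrichment in accessible chromatin against a
    shuffled-placement null, testing proximity of deregulated TE copies to
    deregulated genes against a resampled-gene background, and scoring
    transcription-factor footprint occupancy from Tn5 insertion profiles.
    Includes a synthetic-data generator with recorded ground truth so every
    stage of the pipeline can be verified end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
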