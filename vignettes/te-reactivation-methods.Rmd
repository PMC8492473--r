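---
title: "Methods: quantifying transposable-element reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transposable-element reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teresurge)
```

`teresurge` implements the computational chain used to characterise
transposable-element (TE) reactivation after cellular stress: expression
quantification at family and copy resolution, differential calling,
accessibility-peak construction, enrichment of TE families in newly
accessible chromatin, proximity of deregulated TE copies to deregulated
genes, and transcription-factor footprint occupancy. This vignette explains
each model, its assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## Coordinates and containers

All intervals are tibbles with `chrom`, `start`, `end` in the 0-based,
half-open convention (BED's convention), so files round-trip without
off-by-one shifts. Overlap always means at least one shared base pair;
bookended intervals (`end == start`-adjacent) do not overlap, but they do
fuse during consensus merging, matching the default of the standard
interval-merge tools. Overlap machinery is delegated to
`GenomicRanges`/`IRanges` internally; tests verify it against a naive
all-pairs oracle, so the package's behaviour does not silently depend on
that delegation.

## TE quantification

TE copies are grouped into families labelled `name:superfamily:class`
(e.g. `SimTE1:ERV1:LTR`). Because TE copies within a family are
near-identical in sequence, most reads from young families map to many
locations; any quantification must decide what to do with that ambiguity.

* **Copy level** (`count_te_copies()`): only uniquely mapped reads
  (`n_hits == 1`) are counted — the in-silico analogue of a stringent MAPQ
  filter. A unique read overlapping several (possibly nested) copies goes
  to the copy with the largest overlap; exact ties go to the
  lexicographically smallest `copy_id`. A deterministic tie-break matters
  more than which tie-break: it makes counting reproducible and testable.
  Counting is unstranded.
* **Family level** (`count_te_families()`): multi-mappers are kept. Each
  candidate placement is matched to the family whose copy it overlaps;
  placements hitting no copy feed a non-TE sink that is reported, never
  silently dropped. `mode = "uniform"` splits each read's unit weight
  evenly over its placements. `mode = "em"` fits the natural multinomial
  mixture — a read's placement probability is proportional to current
  family abundance — by expectation-maximization from a uniform start,
  stopping after `em_iters` (default 100) iterations or when no family
  weight moves by more than `1e-8`. The EM log-likelihood is non-decreasing
  by construction and is exposed for inspection. Total assigned weight
  always equals the number of reads (mass conservation), which the test
  suite asserts on random inputs.

## Differential testing

`nb_test()` models counts as negative binomial with
`Var = mu + dispersion * mu^2`, the parameterization shared by the
standard count-based differential tools. Samples are normalized by
median-of-ratios size factors (`size_factors()`): each sample's factor is
the median ratio of its counts to the per-feature geometric mean, using
only features nonzero everywhere; if no such feature exists the function
falls back to total-count ratios with a warning rather than failing.

Per feature, dispersion is estimated by the method of moments on
within-group variances, pooled across the two groups. With two or three
replicates per group this estimate is extremely noisy, so it is shrunk
toward the across-feature mean with a prior weight of 10 residual degrees
of freedom, and the Wald statistic on the log fold change (delta-method
standard error) is referred to a t distribution with
`n1 + n2 - 2 + 10` df. This information sharing across features is the
conventional remedy in the field for 2–3-replicate designs; without it the
test is either anticonservative (normal reference) or badly underpowered
(t with 4 df) at these sample sizes. Under global-null simulations
(dispersion 0.1, 3 vs 3, 5,000 features) the raw p < 0.05 rate stays
within [0.03, 0.07], and planted four-fold effects at base mean 500 are
recovered at well over 90% — both properties are pinned by the acceptance
tests, which recompute them on every run.

Features that are zero in every sample are reported `untested` and
excluded from the Benjamini–Hochberg adjustment so they cannot dilute it.
Group means of exactly zero are replaced by 0.5 in the log and standard
error (a continuity correction), and identical groups return a fold change
of exactly 0 with p = 1. Designs with a single replicate in a condition
error unless `allow_no_replicates = TRUE`, which estimates dispersion
across both conditions jointly (inflated by any true signal) and marks the
fit `low_confidence`.

Calls use the field's conventional thresholds: linear fold change ≥ 1.5
(`|log2 fc| >= log2(1.5)`, so an observed log2 fc of 0.58 just misses) and
adjusted p < 0.05. `welch_enrichment()` implements the pull-down
(bait-vs-control) caller: per-element Welch unequal-variance t-test,
*unadjusted* p < 0.05 and fold change *strictly* greater than 1.5, as is
customary for that assay. Whether counts should be library-normalized
first is genuinely open; the default is raw counts, `normalize = "total"`
is available, and the choice is recorded on the result.

## Peak operations

Consensus peaks are the fused union of two peak sets (`merge_peaks()`,
0 bp gap merges). `gained_lost()` classifies each consensus peak by which
input it overlaps: later-only = gained, baseline-only = lost, both =
common; the three sets partition the consensus by construction (an
invariant the tests assert on random fixtures), and a consensus peak
overlapping neither input is treated as a caller error. Peaks shorter than
`min_peak_len` (default 300 bp) are discarded; "smaller than 300 bp" is
read as keeping length ≥ 300, i.e. the boundary is inclusive.
`peak_count_significance()` reuses the NB machinery on per-peak read
counts — one NB engine serves expression and accessibility, a deliberate
simplification over mixing two different count-model implementations.

## TE-family enrichment in accessible chromatin

The question is whether accessibility peaks concentrate near a family's
copies beyond what the family's genomic abundance explains. Copies are
padded by ±1 kb (`te_pad`), and the observed statistic counts peak–copy
overlap *events* (a peak overlapping k padded copies contributes k). Event
counting was chosen over distinct-peak counting because it has a clean
closed-form expectation under uniform placement; `count =
"distinct_peaks"` provides the alternative.

The null (`shuffle_te_null()`, default 1,000 shuffles) re-places every
padded copy uniformly at random within its own chromosome, excluding
masked regions (assembly gaps, blacklist, chrM-like contigs), preserving
lengths exactly; shuffled copies may overlap each other. Keeping copies on
their own chromosome preserves per-chromosome TE abundance — an
interpretation choice, since genome-wide shuffling would also be
defensible. Start positions are drawn exactly uniformly over the feasible
start space (no rejection sampling), so the null mean provably matches the
uniform-placement expectation; the acceptance tests check this against an
independently coded closed form at 3 standard errors.

`enrichment_test()` reports an exact binomial p (each of the `n_peaks`
peaks a trial with success probability `null_mean / n_peaks`; upper tail
for enrichment, lower for depletion) and a hypergeometric p on
base-pair bins (urn = genome bp, successes = padded family bp, draws =
total peak bp). The bp-resolution hypergeometric treats every base as
independent and is therefore strongly anticonservative; it is reported for
completeness, but direction calls use the shuffle-calibrated binomial.
`cross_with_de()` finally flags families that are simultaneously
differentially expressed and enriched/depleted in the peak set — the
families whose transcription and chromatin change together.

## TE-copy/gene proximity

`te_gene_proximity()` asks whether genes near upregulated TE copies are
enriched for deregulated genes. A gene is proximal when its TSS lies
within ±30 kb (`proximity_window`) of an upregulated copy; a distance of
exactly 30 kb counts (boundary inclusive, documented rather than
important). The observed overlap between the proximal set and the
deregulated set is tested two ways: an upper-tail hypergeometric plus
two-sided Fisher test against the gene universe, and an empirical
background that redraws `|DEG|` genes 10,000 times
(`n_resamples_proximity`) from the *remaining* genes — the universe minus
the deregulated set, since redrawing the genes being tested would be
circular; `background = "all"` offers the literal-universe alternative —
and summarises the redraws by their mean, which parameterizes an exact
binomial test on the observed count. Under a fully decoupled null
(proximity and deregulation independent), the rejection rate at
alpha = 0.05 over 500 simulated datasets stays within [0.03, 0.08], which
the acceptance suite verifies with 1,000 resamples per dataset for speed.

`closest_gene()` reproduces the closest-TSS assignment used for annotating
copies: minimal unsigned distance, ties to the first gene in
(chrom, start, gene_id) order, distance signed by the copy's orientation
(positive = TSS downstream of the copy).

## Footprinting

Tn5 insertion events are derived from fragment ends with the ATAC
coordinate correction: +4 bp on the plus strand, −5 bp on the minus strand
(`shift_insertions()`), the standard dyad-centring shift; out-of-bounds
events are dropped and tallied, so event counts reconcile exactly.
`aggregate_profile()` averages per-position counts across motif sites with
strands kept separate — the familiar red/blue footprint profile — with an
optional per-bp-rate normalization (each strand sums to 1).

The footprint occupancy score is the flank-ratio form
`FOS = (C+1)/max(L,1) + (C+1)/max(R,1)`, with `C` the insertions in the
motif span and `L`, `R` those in `flank_width` bp (default 35) immediately
left and right. Lower scores mean deeper protection. The pseudocounts keep
the score positive and defined for empty windows; whether flanks should
scale with motif length is unknowable from convention alone, so
`flank_width` is a parameter. Mean FOS decreases strictly monotonically
across a simulated protection-depth grid 0 → 1 (Spearman rho at −1 in the
acceptance run). `compare_fos()` log2-transforms paired per-site scores
and applies a two-tailed paired t-test, treating each site as the same
region in both conditions; identical inputs return t = 0, p = 1 rather
than a degenerate error.

## The synthetic-data generator

The generators produce data *with the statistical structure the analyses
assume*, plus recorded ground truth:

* `simulate_genome()`: equal-length chromosomes with ~10 equal excluded
  blocks covering a requested fraction — a caricature of gap/blacklist
  masks.
* `simulate_te_annotation()`: mutually disjoint copies placed uniformly in
  unmasked space; labels follow the `name:superfamily:class` convention.
* `simulate_gene_annotation()`: a chosen fraction of TSSs placed within
  the window of designated copies (pairs recorded as truth), the rest
  strictly farther than the window from all of them.
* `simulate_counts()`: NB counts with per-feature fold changes between two
  conditions; `dispersion = 0` degrades to Poisson; library size factors
  exercise normalization. Defaults (3 replicates, base mean 500 for
  expression and 100 for peaks, dispersion 0.05, planted fold change 4)
  reflect a well-powered bulk experiment; the paper-scale data give no
  usable noise model, so dispersions are conventional values for bulk
  RNA-seq/ATAC-seq, chosen once.
* `simulate_peaks()`: peak starts drawn from the exact hit/miss start
  spaces so that the probability of landing within ±pad of an enriched
  family's copy is precisely `enrichment_factor` times the uniform
  probability — `enrichment_factor = 1` is exactly uniform placement, not
  approximately.
* `simulate_insertion_profiles()`: per-site, per-strand Poisson counts
  with the motif span attenuated by `footprint_depth`.

Every generator is deterministic given its seed (`withr::with_seed`, so
the caller's RNG state is untouched).

What the generator does **not** emulate: mappability structure and
sequence-driven alignment ambiguity (multi-mapper structure is injected
parametrically by `simulate_te_reads()`), GC and accessibility biases,
correlated dispersion trends, overlapping genes/TEs on real genomes,
fragment-length periodicity in insertion data, and single-cell counts.
Passing tests therefore demonstrate that the *procedures* are correct and
calibrated under their stated models — not that any particular biological
dataset will satisfy those models.

## Problem sizes and runtime choices

The default end-to-end run (`run_synthetic_pipeline()`) uses 2 chromosomes
of 1 Mb, 8 families × 25 copies, 300 genes, 150–200 peaks, 3 + 3
replicates, 1,000 placement shuffles, 10,000 gene resamples and 300
footprint sites — sizes chosen so a full run takes on the order of a
minute on one CPU while keeping every planted effect comfortably
detectable and every empirical null smooth. Calibration experiments in the
tests use 5 × 5,000 null features for the NB test and 500 decoupled
datasets × 1,000 resamples for the proximity test.

## Known limitations

* The NB test is a moderated Wald test, not a likelihood-ratio or
  quasi-likelihood GLM; no shrinkage of fold changes, no covariates.
* The bp-bin hypergeometric enrichment p ignores base-pair dependence and
  should be read as descriptive.
* EM family quantification resolves ambiguity by abundance only; it does
  not model positional or quality information and is not a bit-for-bit
  reproduction of any external quantifier.
* Footprint site discovery is out of scope: motif sites are an input.
* Interval semantics are strand-blind everywhere except the sign of
  `closest_gene()` distances and the Tn5 shift.
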