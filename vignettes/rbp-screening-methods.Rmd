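---
title: "Methods: screening for RNA-binding proteins from microarray data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for RNA-binding proteins from microarray data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpscreen)
```

## The screening problem

Hundreds of proteins beyond the canonical RNA-binding proteins (RBPs) —
notably metabolic enzymes — can associate with cellular RNAs. rbpscreen
implements a complete computational screen for such proteins in budding
yeast, in five stages:

1. **Protein-microarray binder selection.** Thousands of purified
   proteins, spotted in duplicate, are probed with fluorescently
   labelled RNA; the analysis must decide which proteins reproducibly
   bound the probe across replicate arrays.
2. **RIP-Chip target calling.** For selected candidates, RNAs
   co-purifying with the tagged protein are compared against mock
   purifications from untagged cells on two-color DNA microarrays.
3. **Enrichment statistics.** Target and binder sets are tested for
   over-represented GO terms and Pfam domains against an explicit
   background.
4. **Overexpression profiling.** Whether a candidate regulator shifts
   the expression of its experimentally defined targets is quantified
   from replicate overexpression-vs-control profiles.
5. **Expression-compendium clustering.** Candidate RBPs are grouped by
   their expression profiles across hundreds of conditions.

Every stage can be exercised on synthetic data with known ground truth
(the `gen_*` generators), which is how the test suite validates
parameter recovery, false-positive calibration, and the exactness of
the statistical primitives.

## Binder selection from protein arrays

### Percentile ranks and the bimodal trough

Replicate protein arrays probed with complex RNA pools vary in signal
magnitude and scale, so absolute intensities are not comparable across
replicates. Each array is therefore reduced to ascending percentile
ranks in (0, 1] (`percentile_rank()`, tie-averaged: tie conventions
differ across scanner software, and tie-averaging is the choice that
keeps the rank sum invariant). Per protein, the median rank across replicates
(`median_rank_profile()`) is high only for proteins *consistently*
near the top of every array. When a subpopulation of true binders
exists, the distribution of median ranks is bimodal: a broad
non-binder mode and a high-rank binder mode. The trough between the
modes is a conservative binder cutoff; selection is strictly above the
cutoff (`select_binders()`).

`find_trough_cutoff()` automates what is usually done by eye:

* counts are histogrammed at `hist_bin_width` (default 0.01) inside
  `trough_search_interval` (default [0.5, 1]);
* counts are smoothed with a centred 5-bin moving average — raw
  0.01-wide bins carry enough Poisson noise to fake local maxima on a
  flat background;
* the two modes are the pair of local maxima enclosing the most
  *prominent* valley, measured as the drop from the lower mode to the
  valley floor relative to the lower mode's height. This is robust
  where "the two tallest maxima" is not: on a flat background mode the
  two tallest smoothed bins are adjacent noise bumps.
* a histogram is declared unimodal (an error instructing use of
  `cutoff_override`) when no valley reaches a relative depth of 0.35.
  The threshold separates the two regimes by a wide margin: across
  simulated unimodal rank sets the deepest spurious valley reached
  ~0.29, while genuine two-component mixtures never fell below ~0.42.

The cutoff is the midpoint of the lowest-count bin strictly between
the modes (centre of the minimal run under ties). On two-component
mixtures with a known empty valley the detector recovers the valley
midpoint exactly across 100 seeds; the test suite asserts within
±2 bins. `cutoff_override` bypasses detection entirely, which is also
how published manual cutoffs (e.g. 0.90 / 0.95) are reproduced.

### Z-score mode for single-RNA probes

Probings with one defined short RNA are reproducible enough for
absolute scores. `zscore_select()` standardizes each array
(`Z = (x − center)/SD`) and selects features exceeding the threshold
(default 3.5) in *every* replicate; `require_all_replicates = FALSE`
thresholds the replicate-mean Z instead. The centering statistic
defaults to the median — robust to the handful of genuine binders in
the upper tail — with `center = "mean"` available because both
conventions appear in practice; a message states which centre is in
use. Z-mode selection is invariant under per-array affine transforms
with positive scale, rank mode under any strictly increasing
transform; both invariances are property-tested.

## RIP-Chip target calling

### Quality filters

`qc_filter()` masks spots whose input-channel signal over background
is at or below 1.8 (retention is strictly above the threshold) and
drops features with data in no more than 60% of the arrays (a feature
present in 5 of 8 arrays, 62.5%, is retained; 4 of 8 is not). Both
thresholds are config-exposed (`rip_config()`), and the filter report
records masked and dropped counts.

### The regularized t-statistic

With 3 IP and 5 mock arrays, per-feature variance estimates are
unstable; the classical remedy is to shrink them toward a prior
estimated from features of similar expression. `local_sd_prior()`
sorts features by group mean and averages sample SDs in a sliding
window of `w = 101` features. Windows are *clamped* at the sorted ends
(the first window is the first `w` features), never reflected, so
every prior averages exactly `w` observed SDs. `regularized_t()` then
uses the posterior variance

$$\hat\sigma^2 = \frac{\nu_0\,\sigma_0^2 + (n-1)\,s^2}{\nu_0 + n - 2},$$

a Welch-style statistic with per-group posterior variances, and
$df = n_1 + n_2 - 2 + 2\nu_0$ (the prior contributes pseudo-
observations; `df_augmented = FALSE` gives the classical df). Defaults
$\nu_0 = 10$, $w = 101$ follow the established conventions for this
family of tests and are exposed in `rip_config()`.

At $\nu_0 = 0$ the test is *defined* as the ordinary two-sample t with
per-group sample variances (the formula above would instead give
$(n-1)s^2/(n-2)$; the classical limit is the correct reference
behaviour, so $\nu_0 = 0$ is special-cased). Consequently the
statistic is continuous in $\nu_0$ on $(0, \infty)$ with a small
definitional step at 0; tests cover the closed form to 1e-10, the
$\nu_0 = 0$ equivalence, and monotone shrinkage toward the
prior-dominated value.

`call_targets()` combines the fold change $2^{\bar x_{IP} - \bar
x_{mock}}$ (means of available post-QC log2 ratios per group, i.e. the
geometric-mean convention) with the regularized-t p-value: a target
needs fold ≥ 3 (inclusive) *and* p < 0.01. Under a pure null
simulation the empirical false-positive rate at p < 0.05 and p < 0.01
matches the nominal level within 3 binomial standard errors, and no
feature passes the joint fold+p criterion; at 4-fold spiked
enrichment with noise SD 0.4 the caller recovers >90% of true targets
with essentially no false discoveries.

## Enrichment statistics

`hypergeom_upper_tail()` is the exact upper-tail hypergeometric
probability via `stats::phyper` (log-space combinatorics; validated
against a brute-force enumeration oracle for every N ≤ 25 to 1e-12).
`enrich_terms()` tests every term with at least one sample hit against
an explicit, caller-supplied universe — the set of proteins on the
array for domain tests, or the set of features with microarray data
for GO tests over RIP targets — and applies Bonferroni over the number
of terms actually tested. Universe, sample size and multiplier are
logged on every run because published enrichment p-values are
notoriously sensitive to these conventions; no attempt is made to
reproduce annotation-version-dependent counts.

## Overexpression profiling

`oe_qc_filter()` masks spots below S/B 2.0 in *either* channel and
applies the regression-correlation criterion. The conventional QC
direction is to keep high-correlation spots (`keep_above`, default),
but the opposite reading (`keep_below`) is provided because the
filtering direction of this criterion is genuinely ambiguous in parts
of the literature; both policies are exercised in tests.

`gene_stats()` gives per-gene mean log2 ratio, fold change
$2^{\text{mean}}$ (fold < 1 is down-regulation), and a two-sided
one-sample t against mean 0 with n−1 df. Genes with identical nonzero
replicates have no defined t; they are flagged rather than assigned a
silent p = 0. `changed_genes()` uses reciprocal fold boundaries
(≥ 1.5 up, ≤ 1/1.5 down) with p < 0.05.

`target_shift()` quantifies a coordinated shift of a target set: the
mean fold change over targets is reported under *both* conventions —
arithmetic mean of per-gene linear fold changes (`mean_fc_targets`)
and back-transformed mean log2 (`mean_fc_targets_geom`) — because the
choice is rarely stated in publications and the two differ slightly
under noise. Significance is a two-sided Mann–Whitney U on per-gene
mean log2 ratios (exact for small untied samples, normal approximation
otherwise), plus cumulative-distribution tables for plotting.
`overrep_fisher()` tests target over-representation among changed
genes with the two-sided probability-mass Fisher exact test
(`stats::fisher.test`, validated against table enumeration to 1e-12).

## Expression-compendium clustering

`kmeans_profiles()` clusters genes by their condition profiles:
Lloyd's algorithm under the Euclidean metric with k-means++-style
seeding, 25 restarts keeping the lowest within-cluster sum of squares,
and empty clusters re-seeded from the point farthest from its
centroid. The run is deterministic given `seed`. The companion
`class_expression_test()` compares two disjoint gene classes by their
per-gene median expression with a two-sided rank-sum test.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* `gen_protoarray()` — log-normal background fluorescence (strictly
  positive, right-skewed); binders injected by *rank*: per replicate a
  binder's level is the background distribution's quantile at a level
  drawn uniformly above `binder_rank_floor` (default 0.92), times
  multiplicative noise. Rank injection, rather than an additive
  effect, matches the rank-based screen statistic. Defaults (1,000
  proteins, 5 replicates, 5% binders, noise SD 0.1) give a clearly
  bimodal median-rank histogram with the valley near 0.87–0.89.
* `gen_ripchip()` — Normal(0, 0.4) log2 ratios, targets shifted by
  `log2_enrichment` in the IP group only (default 2, i.e. 4-fold,
  with 3 IP and 5 mock arrays); ~2% of spots per array get S/B below
  1.8 to exercise QC.
* `gen_overexpression()` — targets centred at `log2(0.925)`, the
  driver at `log2(4.2)`, 3 replicates with noise SD 0.2 — a slight
  coordinated down-shift of a 100-gene target set among 6,000 genes,
  detectable by the Mann–Whitney test but far below per-gene
  significance.
* `gen_compendium()` — block-structured profiles: 10 blocks of a
  164 × 247 matrix around a common baseline, centroid coordinates
  Normal(0, separation), unit within-block noise.

What the generators deliberately do **not** model: spatial array
artifacts, dye bias, probe-sequence effects, correlated noise between
features, cross-hybridization, or protein folding state on the slide.
Passing spike-in tests therefore demonstrates that the statistics
recover the structure they are designed for at realistic noise levels
— not that real arrays are free of the systematic effects that
normalization and experimental design must handle upstream.

## Numerical choices and degenerate inputs

* Missing values are represented as `NA`, never zero; every statistic
  states its policy (presence filters, per-feature group n, dropped
  genes in clustering).
* Boundary conventions are strict where the text of the corresponding
  threshold is strict: S/B must *exceed* 1.8 (2.0), presence must
  *exceed* 60%, rank selection is strictly *above* the cutoff; fold ≥
  3.0 is inclusive ("at least 3-fold").
* Degenerate inputs error loudly: zero-SD arrays in Z mode, unimodal
  histograms in trough detection, both-groups-constant with
  $\nu_0 = 0$, overlapping classes in the compendium comparison.
* Problem sizes in the test and acceptance runs (1,000-protein arrays,
  6,000-feature RIP and overexpression sets, 10–100 seed repetitions)
  are chosen so each property is measured with comfortable binomial
  margins while the full suite runs in well under a minute.

## Known limitations

* Trough detection assumes the two modes are separable at the chosen
  bin width; very small binder fractions (< ~1%) may not form a
  detectable second mode — use `cutoff_override`.
* The regularized t assumes approximately normal log2 ratios and a
  smooth variance–mean relationship; heavy-tailed contamination will
  inflate the local SD prior.
* Published target lists from deposited datasets are only
  qualitatively reproducible: the exact hyperparameters of the
  original regularized-t runs are not recorded, so acceptance for the
  RIP stage rests on oracle equivalence and spike-in recovery.
* Enrichment results depend on the annotation file supplied; the
  package performs no GO DAG propagation beyond what the file encodes.
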