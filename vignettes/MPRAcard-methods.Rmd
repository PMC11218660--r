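---
title: "MPRAcard: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MPRAcard: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MPRAcard)
```

MPRAcard analyses massively parallel reporter assays (MPRAs) of candidate
cardiac enhancers and noncoding de novo variants. This vignette is the
package's own account of the statistics it implements: the models, their
assumptions, the tunable parameters that matter, and the places where the
design was genuinely open and a choice had to be made.

## The measurement model

An MPRA couples each tested sequence to a barcode and reads activity out as
the barcode's abundance in RNA relative to the DNA library that was
delivered to the cells. The package models barcode counts as negative
binomial with variance `mu + alpha * mu^2`, the standard overdispersed count
family for sequencing data; `alpha` (the dispersion) captures
biological-replicate noise that does not vanish with sequencing depth.

Activity is summarized two ways, mirroring how these assays are analysed in
practice:

- a descriptive score, `log2((RNA_fpm + 1) / (DNA_fpm + 1))`, averaged over
  replicates (FPM = fragments per million; the pseudocount of 1 keeps
  zero-count designs finite), and
- an inferential call from a count model (next section).

Designs are kept only when DNA coverage reaches 20 FPM in at least one
replicate library. The filter deliberately uses DNA only: a design with
good DNA representation but no RNA signal is informative (it is inactive),
whereas a design absent from the DNA library was simply not assayed.

## Active-enhancer calling

For each design, RNA and DNA counts are treated as two experimental
conditions within each replicate, and a negative-binomial log-linear model
with replicate fixed effects plus a material (RNA vs DNA) coefficient is
fit by iteratively reweighted least squares. Library size factors
(median-of-ratios over designs with nonzero counts everywhere) enter as
offsets. The material coefficient's Wald statistic is tested two-sided and
Benjamini–Hochberg adjusted across designs; "active" additionally requires
a positive log2 fold change, i.e. significantly *elevated* RNA.

Numerical choices:

- **Dispersion.** A pooled method-of-moments estimate per design:
  on size-factor-normalized counts, each condition's mean is removed, the
  pooled residual variance `s^2` is compared to the overall mean `mu`, and
  `alpha = max((s^2 - mu) / mu^2, 0.01)`. The floor of 0.01 prevents
  degenerate zero-dispersion fits on designs whose sample variance happens
  to fall below Poisson. This is intentionally simpler than the
  shrinkage-and-trend machinery of dedicated differential-count packages;
  the package's correctness claim is calibration (below), not numerical
  agreement with any particular tool.
- **Reference distribution.** The dispersion is a noisy plug-in estimate,
  so the Wald statistic is referred to a t distribution on the dispersion
  estimate's degrees of freedom (`2k - 2` for `k` replicates), the usual
  quasi-likelihood convention. With a normal reference the test is visibly
  anticonservative at `k = 4` (empirical type-I error near 0.09 at nominal
  0.05); with the t reference it is calibrated (0.045 on 1,000 null
  designs), which the test suite checks within the band [0.03, 0.07].
- **Convergence.** IRLS runs at most 50 iterations to a relative step
  tolerance of 1e-8; non-converged designs are flagged and reported with
  p = 1 rather than dropped.

## REF/ALT differential activity

Allelic effects are tested on per-replicate activity differences
(ALT − REF) with a paired two-sided t statistic on `k - 1` degrees of
freedom, computed in closed form so degenerate inputs degrade gracefully:
zero-variance nonzero differences give p = 0, all-zero differences p = 1,
and fewer than three complete pairs is flagged "undertested" with p = 1.
The log2 fold change is the mean per-replicate difference — consistent
with the paired test — rather than a difference of means over possibly
different replicate sets.

A pair is MPRA-DA (decreased activity) or MPRA-IA (increased) only when all
three gates pass: BH-adjusted p below 0.05 across all pairs jointly (one
family for the whole experiment, not per fragment), `|log2FC| >= 0.58`
(a 1.5-fold change), and detectable activity. "Detectable activity in at
least one sample" is read as: at least one pair member is an active call
from the count model. The alternative reading — nonzero RNA in at least one
replicate — is exposed as `activityRule = "nonzero-rna"` for users who
prefer the weaker gate.

For tiling-deletion libraries, fragments whose wild-type member failed the
coverage filter are dropped entirely before summarizing per-fragment
deletion effects.

## Enrichment scores

For a subset R (size n) of the activity-ranked library L (size N), the
running enrichment score is the cumulative membership fraction minus the
cumulative library fraction:

$$ES_i = \frac{1}{n}\sum_{t \le i} \mathbf{1}[r_t \in R] - \frac{i}{N}.$$

`ES_N = 0` identically, and reversing the ranking negates the mean score
exactly (both verified by enumeration in the tests). The permutation
p-value draws 2,000 random same-size sets and takes the one-sided tail on
the side of the observed mean ES — the proportion of random sets at or
beyond it. Because the side is chosen by the observed sign, the null
distribution of this p is uniform on (0, 1/2), not (0, 1); the calibration
test therefore checks that 2p is standard uniform. The p-value is a pure
proportion (no +1 smoothing), so its resolution floor is 1/B. Bonferroni
correction multiplies by the number of subsets tested in a batch.

The `i/N` form of the final term follows the definition of the score as a
difference of two cumulative probabilities; with `i/n` the curve would not
terminate at zero and the score would lose its depletion symmetry.

## Motif analysis

PWM matches are scored as log2 odds against the background, with a
pseudocount of 1e-3 per matrix cell. Scores are discretized to 1e-3 log2
units, and the match p-value is the exact tail probability of the score
under the background model, obtained by dynamic programming over the
per-position score distributions. The scanner and the null distribution
share one discrete score space, so for short motifs the DP p-values equal
exhaustive enumeration over all 4^L words bit for bit (asserted for
L ≤ 6 in the tests). The best hit is the maximum over all offsets
overlapping the scan window on both strands — a window of ±8 bp around the
variant for REF/ALT libraries and ±10 bp for deletion libraries.

The motif score of an oligo is `-log10(p)` of its best hit (0 when there is
no hit), so a score difference of 2 between REF and ALT is exactly a
100-fold change in match p-value — the threshold for calling a
loss-of-motif (delta ≤ −2) or gain-of-motif (delta ≥ +2). Only motifs with
p < 1e-3 in at least one member of a pair are considered at all.

Per motif, association with activity change is summarized as a signed odds
ratio: with `P_mc` the proportion of activity-changed (MPRA-DA or MPRA-IA)
pairs showing a motif change and `P_mn` the same proportion among MPRA-NS
control pairs,

$$OR = n \cdot \frac{P_{mc}(1 - P_{mn})}{P_{mn}(1 - P_{mc})},$$

with sign `n = +1` when the motif behaves like an activator (gained in
MPRA-IA or lost in MPRA-DA) and `n = -1` for the repressor-consistent
pattern; ties resolve to +1. Zero cells receive Haldane 0.5 smoothing and
are flagged.

## EpiCard

Genomic windows are described by annotation-overlap features: per track,
the overlap length in bp, and for quantitative tracks the length-weighted
mean value and total value (sum of value × overlapped bp) — so features
are additive over a partition of a window, an invariant the tests check.

Models are LASSO fits (`glmnet`, alpha = 1, features standardized
internally, coefficients reported on the original scale) with fivefold
cross-validation and a seeded fold assignment. The final penalty is the
cross-validated `lambda.min` divided by ten — a deliberately conservative
rule that trades sparsity for fit. Consequently the final model retains
many small-coefficient noise features; what it preserves is ranking
quality, and the tests score it on recovery (≥ 4 of 5 planted informative
tracks nonzero) and discrimination (AUC > 0.9 separating active from
inactive regions), not on support size. Support-size monotonicity along
the penalty path is checked separately.

The binary family is L1-penalized logistic regression on active/inactive
labels, and EpiCard scores are reported on the linear-predictor (log-odds)
scale. The probability scale was rejected because cohort score cutoffs
above 1 must be representable; a least-squares fit to 0/1 labels was
rejected as a mis-specified likelihood. Variants are scored on the 200 bp
window centered on the variant; variants too close to a chromosome end for
a full window are skipped with a message.

Cohort burden testing compares case and control ncDNV scores by a
two-sided t-test on means, sets a cutoff at the 95th percentile of the
control scores (quantile type 7, R's linear-interpolation default; the
percentile is a parameter), tabulates above/below-cutoff counts into a
2×2 table summarized by the sample odds ratio `ad/bc` with Fisher's exact
p, and repeats the tabulation on each participant's highest-scoring
variant.

## The synthetic-data generators

All pipeline inputs can be simulated under one `SimConfig`; one master seed
expands into independent per-generator substreams, so regenerating one
input never perturbs another, and every generator is byte-deterministic
under a fixed configuration.

What the generators emulate:

- **Counts.** Gamma-distributed library abundances (uneven oligo
  synthesis); DNA counts NB around abundance × depth; RNA means equal to
  DNA relative abundance × `2^multiplier` × depth with the same dispersion.
  Defaults: 4 replicates, depth 2 × 10^6, dispersion 0.05, 30% of regions
  active with log2 multipliers uniform on [1, 3] — values in the range this
  assay family typically reports (replicate correlations near 0.8–0.95 at
  these settings).
- **Annotations.** Informative tracks overlap a region with probability
  `plogis(qlogis(0.2) + 2.5 · active)` — active regions overlapped at
  e^2.5 ≈ 12-fold odds — while uninformative tracks overlap at the 20%
  base rate independently of activity; values are positive and mildly
  elevated noise.
- **Cohorts.** Per-participant ncDNV counts are negative binomial with
  mean 8.25 and size 11, the parameter pair whose quartiles are exactly
  (6, 8, 11) — a median of eight variants per participant with
  interquartile range 6–11, matching the cohort statistic this library
  design targets. A configurable fraction of case-cohort variants is
  placed inside active regions to emulate a burden signal.

What they do not emulate: read-level sequencing error beyond barcode
mismatches, barcode hopping between similar oligos, GC- or
position-dependent amplification bias, linkage between nearby variants,
and the correlation structure of real annotation compendia (tracks are
conditionally independent given activity). Passing tests on synthetic data
therefore demonstrate the statistical machinery is correct and calibrated
under the stated model, not that the model captures every artifact of a
real experiment.

## Problem sizes used by the test suite

The suite exercises calibration at 1,000 null designs (active caller) and
1,000 null pairs (paired test), power at 200 simulation seeds per setting,
exact-p enumeration at motif lengths 3–6, enrichment-score enumeration at
N ≤ 8 over all subsets, and LASSO recovery at 600 regions × 100 tracks.
These sizes were chosen to make Monte-Carlo margins small relative to the
asserted bounds while keeping the default test run fast on a single CPU.

## Known limitations

- The dispersion estimator does not share information across designs;
  designs with very low counts fall back to the floor and lose power
  rather than borrowing strength.
- Exact PWM p-values assume the background model is position-independent
  and the same on both strands; a strand-asymmetric background would make
  reverse-strand p-values approximate.
- `assignBarcodes()` uses greedy rejection sampling; for barcode counts
  approaching the Hamming-ball packing bound it will refuse rather than
  backtrack.
- The burden odds ratio is the sample OR; no confidence interval is
  reported beyond Fisher's exact p.
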