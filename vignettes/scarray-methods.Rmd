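---
title: "Methods: models, parameters and design choices in scarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in scarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarray)
```

# Scope

`scarray` analyses two-color expression arrays hybridized with material
amplified from very small cell inputs (one to ten cells) against a shared
reference channel. Its purpose is to quantify how faithfully a
single-cell profile recapitulates pooled-cell profiles: which probes are
detected, how detection degrades with input amount, and whether relative
expression is preserved among commonly detected probes. This vignette
documents the statistical models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the methodology was genuinely open.

# Quality control

## Dixon's Q test

Small-sample outlier screening uses the classic r10 ("Dixon's Q")
statistic: for a sorted sample, the gap between the suspect extreme value
and its nearest neighbour divided by the range. With at most ten
replicates per group this is the standard choice; more elaborate r11/r21
variants only pay off at larger n.

Critical values are obtained by Monte-Carlo simulation of the statistic
under an i.i.d. standard-normal null (default 10^5 draws, cached per
(n, sidedness, seed)) rather than from published tables. This supports
any (n, alpha) pair, makes the null fully explicit, and — importantly —
lets the *two-sided* test simulate the null of `max(Q_low, Q_high)`, so
its type-I error stays at the nominal alpha instead of doubling. The
statistic is location- and scale-invariant, so no standardization of the
data is needed. Default alpha is 0.05, two-sided; the QC criteria (yield,
labeling efficiency, housekeeping Cq, and the five log2 signal
distribution summaries: 25th/50th/75th percentile, maximum, MAD) are
applied independently, each within a cell-count group, with no
multiplicity correction — a sample flagged by any criterion is excluded.
Groups with fewer than three samples cannot be scanned and are skipped
with a recorded warning.

## Fragment size

The Bioanalyzer "mean fragment size" is the nt value at which the
cumulative trapezoidal area under the fluorescence trace first reaches
50% of the total, interpolating the cumulative area linearly between
grid points. It is invariant to uniform rescaling of the fluorescence.

# Normalization chain

Steps are applied in a fixed order; the provenance record in every
`NormalizedSet` lists them with parameters.

1. **Day-effect correction.** Raw inspection of such experiments shows an
   additive day-to-day processing shift. Within each cell-count group and
   each channel separately, the mean difference between the two
   experimental days is estimated and subtracted from the second day's
   arrays. The correction is additive on the linear signal scale (an
   option exists to skip it); being estimated within group, it cannot
   distort between-group comparisons. Designs with more than two days per
   group are rejected rather than silently chained.
2. **Normexp background correction, offset 50.** Observed intensity is
   modelled as normal background plus exponential signal. Parameters are
   estimated from the signal distribution: the background mean is the
   steepest-ascent point of a kernel density of the low-intensity region
   (bandwidth from the lower quartile; the density is evaluated only up
   to the 75th percentile so the heavy signal tail cannot make the grid
   coarser than the bandwidth). This point sits within about one
   background-sd of the true background mean both when a background
   cluster dominates the data and when the exponential tail does — a
   plain mode or three-moment fit fails in one regime or the other (the
   third central moment of a heavy-tailed signal drives the moment
   system's background mean far negative). The background sd comes from
   the residuals left of the estimated mean, and the exponential mean
   from what the overall mean leaves over. A point mass at the signal
   floor (possible in noise-free simulations) is treated as a degenerate
   background. Each intensity is then replaced by the closed-form
   posterior mean of the signal given the observation (evaluated on the
   log scale for tail stability) plus the offset 50, which stabilizes
   the variance of low signals. Output is strictly positive and strictly
   increasing in the input. Saddle-point maximum likelihood was
   deliberately left out of scope: the simpler estimator is transparent,
   and tests compare its output against a numerical-integration oracle of
   the conditional mean.
3. **Within-array loess.** A robust local-linear trend (degree 1, tricube
   weights, 4 robustness iterations, span 0.30) of M on A is subtracted
   from M. Background correction must precede loess — the normexp model
   is meaningful only on signals still carrying additive background — and
   loess acts on M rather than the raw channels, the standard practice
   for two-color arrays. The span is a conventional default; no span was
   dictated by the methodology being reproduced.
4. **Between-array quantile normalization.** Classic algorithm on log2
   values, applied to the sample channel within each cell-count group
   (arrays of different input amounts are *not* forced onto a common
   distribution, which would erase exactly the dropout signal under
   study). The reference channel is shared by design and is left alone by
   default (`quantile_channels = "both"` covers the alternative, since
   the original description does not say which channels were normalized
   or on which scale). After the step, each group's arrays have
   identical sorted log2 vectors to 1e-9, which is tested as an exact
   property.

After the chain, M and A are recomputed from the final matrices.

# Detection and concordance

A probe is **detected** in a group when its across-array mean normalized
sample-channel signal strictly exceeds 300 (linear scale). The averaging
uses only arrays surviving QC; control probes are excluded from the
universe. The strictness of the inequality is tested at the boundary.

**Sensitivity** of a test profile against a gold standard is the fraction
of gold-detected probes also detected in the test profile; **specificity**
is the fraction of gold-undetected probes also undetected. The
"unexpressed" universe is all non-control probes on the platform not
detected by the gold standard — the methodology being reproduced does not
break its denominators out further. Intervals are equal-tailed 95%
credible intervals from the Beta(s+1, f+1) posterior of a proportion
under a uniform prior (s concordant, f discordant); equal tails rather
than HPD, matching common reporting practice and giving closed-form
checks at (s, f) = (0,0) and (10,0).

**M-ratio statistics** are restricted to probes detected in *all*
compared groups, since a log-ratio against the reference is meaningless
where the sample channel is background. Pearson and Spearman correlations
act on per-probe mean M. The **random-pair difference** statistic samples
`n_pairs` (default 10,000) distinct unordered probe pairs uniformly
without replacement from the shared detected set — pairs are drawn as
indices into the full pair enumeration, so with `n_pairs` equal to the
total pair count the exhaustive statistic is reproduced exactly — and
correlates the within-group differences `M_i − M_j` across groups. The
sampled pair list and seed are returned for reproducibility.

The **pairwise outlier scan** computes all pairwise Pearson correlations
of per-array M vectors within a group, averages each array's correlation
to the others, and hands those means to Dixon's Q.

**Clustering** selects the top 1,000 probes by variance of log2 AF3 and
clusters arrays with average linkage on 1 − Pearson distance; the tree
is exportable as Newick. **Rank percentiles** place a gene's mean signal
within the full probe distribution of a group (max over the gene's
probes; whole-percentile rounding by default).

# Gene set enrichment

Each group yields a single ranked list: per-gene mean log2 AF3
(probe-to-gene collapse by maximum mean signal; ties broken
lexicographically so the list is deterministic), mean-centered across
genes. The enrichment score is the signed extremum of the weighted
Kolmogorov–Smirnov running sum with weight exponent p = 1 (the classic
default; p = 0 gives the unweighted statistic); a set covering the whole
list takes ES = +1 by convention.

Because each group contributes one ranked list, the permutation null is
**gene-label** permutation (phenotype permutation requires per-sample
class labels, which do not exist here): each permutation redraws the
member positions of each set uniformly. NES divides ES by the mean
absolute null ES of matching sign; the nominal p is the same-sign null
tail proportion; FDR q follows the sign-stratified ratio of null to
observed NES tail proportions, clipped to [0, 1]. All of it is seeded
and reproducible. Patient-vs-patient comparisons, where the original
methodology is under-specified, would be run as gene-permutation GSEA on
the difference of mean-centered profiles; this package exposes the
building blocks but takes no position on the biology.

# qPCR validation arm

Per (sample, gene), the mean Cq over amplified triplicates is normalized
to the RPL13A housekeeping gene: ΔCq = meanCq(gene) − meanCq(RPL13A),
relative expression `2^(−ΔCq)`. A gene is called detected in a sample
when **at least 2 of 3** triplicates amplify within 46 cycles: the
46-cycle bound and triplicate design are given, the replicate rule is
not, and a majority rule is robust to single-well failures without
letting one spurious amplification create a detection. Means use
amplified replicates only. Sample failure is flagged by a Dixon scan of
each sample's mean housekeeping Cq (ACTB, RPL13A, YWHAZ, GAPDH) within
its comparison group.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with ground truth, so every stage is testable offline:

* a fraction `frac_expressed` (default 0.64, matching roughly two thirds
  of probes detectable from bulk material on such platforms) of
  non-control probes is truly expressed, with reference abundance
  `lambda_g` log-normal (`abundance_logmean = log 10`,
  `abundance_logsd = 1.6` — a realistic several-decade dynamic range of
  transcripts per cell);
* the profiled cells differ from the reference pool: each expressed
  probe carries a true log2 sample-vs-reference ratio
  `delta_g ~ N(0, 1)`, shared across cell-count groups because every
  group samples the same cell population — this is the structure the
  M-ratio concordance statistics measure;
* a k-cell sample draws `Poisson(k · lambda_g · 2^delta_g)` transcripts,
  each surviving capture/amplification independently with probability
  `capture_prob` (default 0.3). Dropout is thus modelled at the
  transcript level — the probability of losing a probe entirely is
  `(1 − p)^count` — so low-abundance genes drop out first and detection
  counts rise with cell number, the qualitative behaviour observed in
  such experiments. No quantitative dropout rates per abundance stratum
  were available to calibrate against; defaults were chosen once to
  reproduce the qualitative ordering and left alone;
* signal is `gain · captured_count · lognormal(0, 0.25) + floor +
  day_shift`, with a nonspecific background floor `N(50, 15)` truncated
  at zero (well below the detection threshold of 300, mirroring the
  observation that template-free amplification still yields measurable
  product) and additive day-2 shifts per channel (defaults 30/20) that
  the day-correction step must recover; the reference channel measures
  `gain · lambda_g` with its own noise and floor and is shared across
  arrays;
* qPCR plates use `Cq = 30 − log2(k · abundance · capture_prob)` plus
  replicate noise, with all-or-none amplification decided by the same
  Poisson-binomial capture draw and a 46-cycle censoring limit; traces
  for fragment-size analysis are smooth unimodal bumps with a seeded
  asymmetry.

Every generator is fully determined by its seed.

**What it does not emulate:** amplification chemistry and its
sequence-specific bias, spatial array artifacts, print-tip effects,
probe-level cross-hybridization, or correlated (non-independent) capture
of transcripts. A green test therefore establishes that the *analysis*
behaves correctly on data with the assumed structure — not that the
assumed structure exhausts real single-cell amplification data.

# Numerical choices and degenerate inputs

* Quantile normalization resolves ties by averaging the bracketing
  reference order-statistic means; a single-array group is returned
  unchanged with a warning.
* `normexp_correct` on an all-equal vector returns `x − min + offset`
  with a warning; `loess_normalize` requires ≥ 10 points;
  `quantile_normalize` rejects non-finite log2 input.
* Dixon's Q rejects n outside 3..30 and zero-range input; `alpha ≥ 1`
  yields critical value 0 by convention.
* The electropherogram 50%-area point accepts non-decreasing (not
  strictly increasing) grids, so piecewise-constant test traces with
  step discontinuities are representable.
* All seeded operations restore or do not disturb the caller's RNG state
  where cached (Dixon null draws), and the pipeline fans one global seed
  into fixed per-stage seeds, keeping each stage individually
  reproducible and every value below 2^31.

# Test-world calibrations worth knowing

Two fixtures are deliberately *designed*, not tuned:

* the noise-free recovery fixture sets `gain = 1000` (above the
  detection threshold) so that a single captured transcript is
  detectable; otherwise the noise-free criterion would conflate
  threshold calibration with capture dropout, which it is not meant to
  measure;
* the day-shift recovery fixture uses 8,000 probes and 10 replicates so
  the Monte-Carlo standard error of the recovered shift (~3 signal
  units) sits well inside the ±10-unit assertion band; power analysis,
  not post-hoc widening.

# Known limitations

* The normexp estimator targets the background location to within about
  one background-sd; arrays whose background is strongly skewed or
  multi-modal will be corrected less accurately than a full MLE would
  allow.
* Specificity on synthetic data is near 1 by construction (unexpressed
  probes receive only floor signal); real nonspecific hybridization can
  produce false detections the generator does not model.
* GSEA FDR uses the sign-stratified pooled-null ratio; with very few
  gene sets the q-values are coarse.
* The pipeline assumes at most two experimental days per group and one
  shared reference channel throughout.
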