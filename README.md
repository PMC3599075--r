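# scarray

Concordance analysis of single-cell two-color microarray profiles.

## The problem

Circulating and disseminated tumor cells are typically recovered in
numbers too small (often < 10 cells, sometimes one) for standard
transcriptome profiling, so the mRNA of a single cell must be amplified
~10^7-fold before hybridization to an expression array. The scientific
question is whether a profile amplified from **one** cell faithfully
recapitulates the profile of pooled 5- or 10-cell samples from the same
population — i.e. how much is lost to transcript capture dropout, and
whether what *is* detected preserves relative expression.

`scarray` implements the full analysis for such experiments on two-color
arrays (sample channel AF3, shared reference channel AF5):

* **QC** — Dixon's Q outlier test (gap-to-range statistic `Q = gap /
  range`) on cDNA yields, labeling efficiency, housekeeping Cq, and five
  per-array signal-distribution summaries, with Monte-Carlo critical
  values under a normal null; Bioanalyzer mean fragment size as the
  50%-cumulative-area point of an electropherogram.
* **Normalization** — additive experimental-day batch correction per
  group and channel; normal + exponential (normexp) background
  correction with offset 50; within-array loess of M on A
  (`M = log2(AF3/AF5)`, `A = ½·log2(AF3·AF5)`); between-array quantile
  normalization within each cell-count group.
* **Detection & concordance** — a probe is detected when its across-array
  mean normalized AF3 signal exceeds 300. Sensitivity and specificity of
  the single-cell profile against a pooled-cell gold standard, with
  equal-tailed credible intervals from the Beta(s+1, f+1) posterior under
  a uniform prior; Pearson/Spearman correlation of M-ratios; Pearson
  correlation of 10,000 random-pair M-ratio differences; pairwise-
  correlation outlier scan; hierarchical clustering of the top 1,000
  most-variable genes.
* **GSEA** — weighted Kolmogorov–Smirnov enrichment score on
  mean-centered log2 intensities, gene-label permutation NES, and
  sign-stratified FDR q-values.
* **qPCR validation** — triplicate Cq aggregation, ΔCq against RPL13A,
  relative expression `2^(−ΔCq)`, detection counts, and housekeeping-
  based failure flagging (46-cycle limit).
* **Synthetic data** — a seeded generator emulating per-probe reference
  abundance, Poisson transcript sampling with binomial capture dropout
  (so low-abundance genes drop out first as input cells decrease), a
  nonspecific background floor, per-channel day shifts, and lognormal
  measurement noise — with ground truth, so every stage is testable
  offline.

## Worked example

```r
library(scarray)

cfg <- sim_config(n_probes = 4000, seed = 11)      # 1/5/10-cell groups, 10 replicates each
es  <- simulate_experiment(cfg)
ns  <- run_preprocess(es)                          # day -> normexp -> loess -> quantile
det <- lapply(c("1", "5", "10"), function(g) call_detection(ns, g))
names(det) <- c("1", "5", "10")

rep  <- sensitivity_specificity(det[["1"]], det[["10"]])
prof <- m_ratio_profile(ns, det[c("1", "10")])
rep$pearson  <- m_ratio_correlations(prof, "pearson")
rep$spearman <- m_ratio_correlations(prof, "spearman")
rp <- random_pair_difference_correlation(prof, n_pairs = 10000, seed = 11)
rep$pair_diff_pearson <- rp$coefficient; rep$n_pairs <- rp$n_pairs
rep
```

prints

```
DetectionProfile '1': 1820 / 3960 probes detected (threshold 300, 10 arrays)
DetectionProfile '5': 2168 / 3960 probes detected (threshold 300, 10 arrays)
DetectionProfile '10': 2275 / 3960 probes detected (threshold 300, 10 arrays)
Concordance 1 vs gold 10 (universe 3960 probes)
  sensitivity 0.800 [0.783, 0.816]  specificity 1.000 [0.998, 1.000]
  M-ratio Pearson 0.943, Spearman 0.937, random-pair diff 0.943 (10000 pairs)
```

Reading: single-cell arrays detect fewer probes than 10-cell arrays
(1,820 vs 2,275 of 3,960 — capture dropout), but 80% of the probes the
10-cell gold standard calls expressed are recovered, essentially nothing
is falsely detected (specificity ≈ 1), and for commonly detected probes
the relative expression (M-ratios and their gene-to-gene differences) is
strongly preserved (r ≈ 0.94).

The whole pipeline (QC → normalize → detect → concordance → clustering →
GSEA → qPCR) runs from one config:

```r
res <- run_pipeline(run_config(sim = cfg, seed = 11), "my_run")   # writes TSV/JSON reports
```

or from the command line via the installed `exec/scarray` script
(`scarray run --out my_run --probes 4000 --seed 11`).

## Package layout

* `R/array_io.R` — TSV/GMT readers and writers, `ExperimentSet` container
* `R/simulate.R` — synthetic experiments, qPCR plates, electropherograms
* `R/qc.R` — Dixon's Q, multi-criteria outlier scans, fragment size
* `R/preprocess.R` — the four-step normalization chain
* `R/concordance.R` — detection, sensitivity/specificity, M-ratio suite,
  clustering, rank percentiles
* `R/gsea.R` — ES/NES/FDR and cross-group NES correlation
* `R/qpcr.R` — ΔCq analysis and detection counts
* `R/pipeline.R`, `R/cli.R` — orchestration and CLI
* `vignettes/scarray-methods.Rmd` — models, assumptions, parameter
  choices, limitations
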