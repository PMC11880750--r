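---
title: "Deriving and validating a microvessel-density gene signature"
author: "mvdsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a microvessel-density gene signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvdsig)
```

## The problem

Microvessel density (MVD) — the number of stained blood vessels per unit
tumor area on an immunohistochemistry (IHC) section — tracks how strongly
a tumor depends on angiogenesis, and with it the likely benefit of
antiangiogenic therapy. IHC, however, needs tissue, is labor-intensive,
and is absent from the large public expression cohorts where biomarker
hypotheses are cheapest to test. `mvdsig` implements a pipeline that
derives a small transcriptomic surrogate for MVD and puts it to work:

1. **Marker discovery.** From a clustered tumor single-cell RNA-seq
   dataset, find genes enriched in the endothelial-cell (EC) cluster:
   per-gene two-sided Mann–Whitney rank-sum tests of the EC cells against
   all other cells on library-size-normalized expression, Benjamini–
   Hochberg correction across all genes, and the filter
   *adjusted p < 0.05 and log2 fold change > 1* (both strict).
2. **Correlation ranking.** Across a panel of tumor models with paired
   bulk RNA-seq (TPM) and MVD(IHC), rank the EC-related genes by the
   Pearson correlation of per-model mean `log2(TPM + 1)` with per-model
   mean MVD(IHC); keep the top 20 by *signed* r.
3. **Specificity filter.** Keep pool genes (top-correlated plus any
   canonical EC markers supplied by the user, e.g. *Kdr*, *Cdh5*, *Tek*)
   whose single-cell expression is concentrated in the EC cluster, and
   truncate to a six-gene signature.
4. **Scoring.** The MVD gene score of a bulk sample is the mean of
   `log2(TPM + 1)` over the signature genes. Any gene set can be scored
   the same way — in particular a T cell–inflamed gene expression profile
   (Tcell_inf_GEP), the second axis of the subgroup classification — and
   an optional per-gene weight vector turns the score into a weighted
   mean for externally published signatures that define one.
5. **Subgroups and efficacy.** Samples are classified into the four
   MVD × Tcell_inf_GEP quadrants by strict comparison against per-axis
   thresholds (cohort medians, or a top-quartile rule for the 12-model
   panel), and antitumor activity is summarized as ΔT/C from per-animal
   growth curves, compared between subgroups by Welch *t* tests.

Because the real datasets behind such a study (animal experiments, IHC
slides, proprietary cohorts) are not portable, the package ships a
synthetic-data module that generates all four input kinds with planted
ground truth, and the entire pipeline is validated by parameter recovery
against that truth.

## The generative model

`make_cluster_profiles()` lays down per-cluster mean expression: every
gene at a common baseline (default 0.5 expected counts per cell, a
typical droplet depth), with each cluster owning a disjoint block of
marker genes raised by a planted log2 fold change. Cluster 1 is the EC
cluster; cluster 2 an immune cluster that drives the planted
Tcell_inf_GEP axis.

`simulate_scrnaseq()` draws counts from a negative binomial with
variance `mu + mu^2/dispersion`. The single shared `dispersion` is the
NB size parameter, so large values approach the Poisson limit — the
convention is chosen so that the limit direction is the intuitive one.

`simulate_panel()` builds each model's bulk profile as a convex mixture
of the cluster means: EC weight `f` (the vascular fraction) and immune
weight `g` are drawn uniformly per model from configurable ranges, the
rest is split equally. Per-gene lognormal noise is applied per replicate
and columns are renormalized to TPM (sums of 1e6, relative tolerance
1e-6). MVD(IHC) is drawn per replicate as `mvd_slope * f + N(0,
mvd_noise_sd)`, truncated at zero. This pseudo-bulk construction — a
mixture of profiles rather than an aggregation of simulated cells — is
deliberate: it is fast and it isolates exactly the signal the pipeline
must find, that bulk EC-gene expression tracks vessel density.

`simulate_growth()` gives each animal
`V(t) = V1 * exp(r * (1 - effect) * (t - 1))` times lognormal
measurement noise, with `V1 = 100` mm³, four arms (NT, drugA, drugB,
combo, 8 animals each), and per-arm effects looked up by the model's
planted quadrant. Noise is multiplicative because volumes are positive
and errors scale with size. Animals crossing 2,000 mm³ are censored:
the crossing measurement is kept, later ones dropped, and arm means use
whoever is still on study — the package's declared convention for a
humane-endpoint rule that real protocols leave unspecified.

## The calibrated reference scenario ("panel12")

`panel12_scenario()` fixes the conditions used throughout the tests:
1,000 genes, 14 clusters with 40 markers each at log2FC 2, 400 cells per
cluster (≈5,600 cells), a 12-model panel with 5 replicates per model, EC
and immune fractions on [0.02, 0.25], `mvd_slope = 1000` (so MVD(IHC)
spans roughly 20–250 vessels/mm², a realistic IHC range),
`mvd_noise_sd = 35` and `bulk_noise_sd = 0.55`. The two noise levels
were calibrated once, by long-run simulation (panels of thousands of
models), so that the population correlation between the derived
six-gene score and MVD(IHC) is 0.80 — a strong but imperfect surrogate,
which is the regime in which a 12-model panel is an honest, noisy
estimator. They were not revisited afterwards.

Two numerical choices deserve emphasis:

* **Specificity threshold.** `build_signature()` defaults to a
  specificity index ≥ 0.5 — appropriate for genuinely near-exclusive EC
  genes in real data. Under the panel12 conditions, however, a marker
  planted at log2FC 2 against 13 other clusters can reach at most
  `2^2/(2^2 + 13) ≈ 0.24` of its expression in EC cells, so the scenario
  carries `specificity_threshold = 0.15` — about twice the uniform share
  of 1/14 — which separates planted markers from background with a wide
  margin while respecting the planted effect size.
* **In-sample versus out-of-sample correlation.** The score–MVD
  correlation reported on the 12-model derivation panel is in-sample:
  the same panel ranks the genes and evaluates the score, so
  winner's-curse selection inflates it (Monte-Carlo over 100 seeds:
  median ≈ 0.95, 90% interval [0.88, 0.98] against a population value of
  0.80). That mirrors how such derivation studies actually report the
  number. Convergence of the estimator is therefore checked
  out-of-sample: the signature derived on the 12-model panel is scored
  on an independent 200-model cohort, where the estimate concentrates
  within ±0.05 of 0.80 (60-seed Monte-Carlo: mean 0.80, range
  0.76–0.84). Estimating on the selection panel at n = 200 would sit
  near 0.85 and never approach the population value.

## Statistical conventions

* **Marker test.** Mann–Whitney with midranks, tie-corrected normal
  approximation and continuity correction; a fully tied gene gets
  p = 1. The implementation is vectorized over genes and is checked
  element-wise against `stats::wilcox.test(exact = FALSE)` in the test
  suite. Null calibration: on 6,000 independent null NB genes
  (100 vs 100 cells) the empirical type-I error at α = 0.05 falls inside
  the binomial 95% band.
* **Fold change.** `log2((mean_T + 1)/(mean_R + 1))` on normalized
  means. The pseudocount of 1 is a declared convention — upstream tools
  document none — and it matters near the threshold: the filter is
  strict (`> 1`), so a gene at exactly log2FC 1 is excluded.
* **BH adjustment** wraps `stats::p.adjust(method = "BH")`, validated
  against a brute-force step-up implementation in the tests. The family
  is always *all* tested genes (no pre-filtering).
* **Correlation p-values** come from the t transform of r on n − 2
  degrees of freedom (identical to `cor.test`); genes with zero
  expression variance are reported NA and excluded from ranking. Ties in
  r are broken lexicographically by gene id, making every ranking
  deterministic.
* **Welch t** wraps `stats::t.test(var.equal = FALSE)`; the degenerate
  case of two constant, equal groups returns t = 0, p = 1 by convention
  rather than erroring, so permutation loops never crash.
* **Quantiles.** The top-quartile rule uses inclusive linear
  interpolation (`quantile(type = 7)`) with *high ⇔ value ≥ threshold*,
  which labels exactly 3 of 12 models high; the quadrant split uses the
  sample median with *high ⇔ score > threshold* (at-threshold samples
  are low). The two conventions are deliberately different — the
  quartile rule must include its boundary to yield 3/12, the median rule
  must exclude it to keep the partition unambiguous at odd n — and both
  are regression-tested.
* **ΔT/C** uses arm means per day:
  `(T_t − T_1)/(C_t − C_1) × 100`, switching to
  `(T_t − T_1)/T_1 × 100` when the treated mean on day t has fallen
  below day 1 (regression; necessarily negative). The ratio branch
  errors when the control change is zero rather than returning an
  infinity.

## What the simulations do and do not show

The generators reproduce the statistical skeleton the analysis relies
on: overdispersed clustered counts, replicate-level bulk noise, an
expression–IHC link with both axes noisy, and subgroup-dependent
treatment effects. They deliberately omit doublets and ambient RNA,
gene–gene correlation beyond the mixture structure, model-specific
library composition, spatial vessel structure, and inter-animal growth
heterogeneity beyond lognormal measurement noise. Passing the recovery
tests therefore demonstrates that the pipeline's logic is correct and
well calibrated under its stated assumptions — not that a six-gene
signature derived from any particular real dataset will transfer across
species or platforms. Cross-species application in particular is left
to the caller: signatures store gene identifiers verbatim, and ortholog
mapping is an explicit, user-supplied step.

Problem sizes in the shipped tests (1,000 genes, ≈5,600 cells, 12 + 200
models, 50-seed power loops) were chosen so the whole suite documents
the method's behaviour while remaining quick to run routinely; all of
the Monte-Carlo bounds cited above were fixed from larger prior runs
before being pinned in the tests.

## Known limitations

* The Tcell_inf_GEP axis is scored by the same unweighted mean-log rule
  unless weights are supplied; the originally published signature uses
  proprietary weights that are not reproduced here, so absolute score
  values are not comparable to publications that use them.
* The rank-sum marker test is the package's specified replacement for a
  proprietary clustering tool's internal test; a negative-binomial exact
  test is a reasonable alternative but is not implemented.
* ΔT/C inference uses Welch tests on per-model values; repeated-measures
  modelling of whole growth curves is out of scope.
* `run_pipeline()` orchestrates the simulated scenario end-to-end. For
  real data, call the stage functions directly with matrices read via
  `read_expression_tsv()` / `read_sparse_counts()` /
  `read_growth_csv()`.
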