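# mvdsig

Deriving a **microvessel density (MVD) gene signature** from tumor
transcriptomics, and using it — together with a T cell–inflamed gene
expression profile (Tcell_inf_GEP) — to classify tumors into
microenvironment subgroups and relate those subgroups to antitumor drug
efficacy.

MVD, the number of stained blood vessels per unit tumor area on an IHC
section, is a surrogate for tumor dependence on angiogenesis and for
sensitivity to antiangiogenic drugs, but it requires tissue and is absent
from public expression cohorts. `mvdsig` is aimed at preclinical and
translational scientists who want a transcriptomic stand-in: it derives a
small gene signature whose score — the mean of log2(TPM + 1) over the
signature genes — tracks MVD(IHC), and validates every step of the
derivation by parameter recovery on simulated data with planted truth.

## The pipeline

1. **EC marker discovery** (`normalize_cells`, `ec_marker_test`,
   `bh_adjust`, `select_ec_genes`): per-gene Mann–Whitney rank-sum tests
   of the endothelial-cell (EC) cluster against all other cells in a
   clustered single-cell dataset, Benjamini–Hochberg correction, and the
   filter *adjusted p < 0.05 and log2 fold change > 1*.
2. **Correlation ranking** (`model_mean_log_expression`,
   `correlate_with_mvd`, `top_correlated`): Pearson correlation of
   per-model mean log expression with per-model MVD(IHC) across a panel
   of tumor models; the top 20 genes by signed *r* go forward.
3. **Signature assembly** (`specificity_index`, `build_signature`):
   candidates (plus optional canonical EC markers such as *Kdr*, *Cdh5*,
   *Tek*) are filtered by their single-cell expression specificity for
   the EC cluster and truncated to a six-gene `signature_def`, which
   records its transform so scores are portable.
4. **Scoring and subgroups** (`signature_score`, `threshold_median`,
   `threshold_top_quartile`, `classify_quadrants`,
   `subgroup_proportions`, `compare_signatures`): score any cohort,
   split each axis at its median (strict `>` = high), and report
   quadrant memberships and per-group proportions.
5. **Efficacy** (`tumor_volume`, `delta_t_c`, `delta_t_c_table`,
   `welch_t`, `compare_high_low`, `score_change_tests`):
   TV = 0.5 × length × width²; ΔT/C = ΔT/ΔC × 100 on arm means, with the
   regression branch (T_t − T_1)/T_1 × 100 when treated volumes fall
   below baseline; Welch *t* comparisons between subgroups, BH across
   models.

A synthetic-data module (`make_cluster_profiles`, `simulate_scrnaseq`,
`simulate_panel`, `simulate_growth`, `panel12_scenario`) generates all
four input kinds — clustered negative-binomial single-cell counts, bulk
TPM panels with paired MVD(IHC), validation cohorts, and per-animal
growth curves — with known planted structure. `run_pipeline()` ties the
stages together on a scenario and writes every intermediate table plus a
reproducible run manifest. See the methods vignette
(`vignettes/mvd-signature-methods.Rmd`) for the model, conventions and
calibration choices.

## Worked example

```r
library(mvdsig)
cfg <- panel12_scenario(seed = 1)          # calibrated reference scenario
res <- run_pipeline(cfg, outdir = "run1")  # ~20 s

res$signature
#> signature_def 'MVD': 6 genes, score = mean of log2(TPM + 1)
#>   genes: g00834, g00418, g00221, g00060, g00824, g00939

mvd   <- tapply(res$panel$samples$mvd_ihc, res$panel$samples$model, mean)
score <- tapply(res$scores$mvd_score, res$scores$model, mean)
cor(score, mvd)
#> [1] 0.943

table(res$quadrants$quadrant)
#> MVD-high/Tcell_inf_GEP-high  MVD-high/Tcell_inf_GEP-low
#>                           2                           4
#>  MVD-low/Tcell_inf_GEP-high   MVD-low/Tcell_inf_GEP-low
#>                           4                           2

subset(res$delta_t_c, model %in% c("M01", "M02") & arm == "drugA")
#>   model   arm day delta_t_c branch_used n_treated n_control
#> 1   M01 drugA  15 53.264014       ratio         8         8
#> 4   M02 drugA  15  7.228221       ratio         8         8
```

The six derived genes are all planted EC markers (the simulator's ground
truth), the in-sample score–MVD correlation on the 12-model derivation
panel is 0.94, and per-model ΔT/C at day 15 reflects each model's
planted treatment effect (lower = stronger growth inhibition; 100 = no
effect). Model-level quadrant labels come from median splits of the MVD
and Tcell_inf_GEP scores.

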