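# loyprs

Polygenic risk prediction of mosaic loss of chromosome Y (LOY) in blood.

LOY is the most common acquired aneuploidy in ageing men: a fraction of
blood leukocytes lose their single Y chromosome, and that mosaic fraction
tends to expand with age. On SNP arrays LOY shows up as a downward shift of
the Log R Ratio (LRR) over the male-specific region of chromosome Y (MSY);
its per-sample summary is the **mLRRY**, the median LRR over the MSY
probes. `loyprs` is for statistical geneticists and epidemiologists who
want to test whether a germline polygenic risk score (PRS) predicts who
carries LOY, end to end:

* **LOY calling from arrays** — mLRRY, an experimental-error calling
  threshold built by reflecting the distribution above its mode (the lower
  0.5th percentile of that symmetric null; ≈ mode − 2.576 σ for Gaussian
  noise), and conversion to the percent of affected cells via
  *f* = 1 − 2^(mLRRY/*c*) with response factor *c* = 0.46, calibrated so
  mLRRY −0.06 ↔ 8.6% of cells.
* **PRS construction** — variant QC (call rate > 90%, Hardy–Weinberg exact
  test, imputation r² ≥ 0.3), allele alignment, the weighted dosage sum
  *s*ᵢ = Σᵥ *w*ᵥ *d*ᵢᵥ, Z-standardisation, and rank-based quintile risk
  groups (low 0–20%, middle 21–80%, high 81–100%).
* **Association & prediction** — logistic models of LOY on the per-SD PRS
  and on risk groups (adjusted for age, current smoking, current alcohol),
  ANCOVA of PRS distributions, age-stratified models, ROC/AUC with
  DeLong confidence intervals, and DeLong's test for correlated AUCs.
* **WGS validation** — read-depth log2 ratio of MSY to half the autosomal
  depth, and Pearson concordance with the array estimate.
* **A seeded synthetic cohort** with known ground truth (true mosaic
  fractions, true generative effects), so every stage is testable without
  access-controlled genotype data.

See the methods vignette (`vignettes/loy-prs-methods.Rmd`) for the models,
assumptions, defaults and limitations.

## Worked example

```r
library(loyprs)

cfg <- sim_config(seed = 1)        # default study conditions: 5131 men, 156 variants
ds  <- simulate_dataset(cfg)
rep <- analyze_loy_dataset(ds)

rep$threshold
#> LOY calling threshold: -0.0437 (method reflected_null, mode -0.0005, n 5131)

rep$counts$n_variants_pass_qc
#> [1] 123

rep$prevalence_by_age
#>   age_bin    n n_loy  pct_loy
#> 1   70-74 3071   650 21.16574
#> 2   75-79 1215   367 30.20576
#> 3   80-84  563   233 41.38544
#> 4     85+  282   154 54.60993

rep$model_per_sd
#> Association model (n = 5131)
#>             term estimate       se odds_ratio    ci_low   ci_high   p_value
#>      (Intercept) -8.68585 0.500253   0.000169 6.338e-05 0.0004504 1.575e-67
#>          z_score  0.52860 0.034915   1.696556 1.584e+00 1.8167185 8.848e-52
#>              age  0.09761 0.006424   1.102529 1.089e+00 1.1164981 3.881e-52
#>   current_smoker  0.84247 0.156499   2.322089 1.709e+00 3.1556679 7.317e-08
#>  current_alcohol  0.21787 0.094822   1.243427 1.033e+00 1.4973828 2.158e-02
```

The threshold estimated from the cohort's own technical noise is −0.044
LRR units; 123 of the 156 score variants survive QC; LOY prevalence climbs
from 21% at ages 70–74 to 55% at 85+; and the fitted odds ratio per SD of
the PRS is 1.70 (CI 1.58–1.82), recovering the generating effect of 1.74.
The quintile contrast and model comparison:

```r
rg <- rep$model_risk_group
rg[grepl("risk_group", rg$term), c("term", "odds_ratio", "ci_low", "ci_high")]
#>              term odds_ratio ci_low ci_high
#>  risk_groupmiddle      1.844  1.527   2.227
#>    risk_grouphigh      4.077  3.294   5.046

c(base = rep$roc$auc_base$auc, full = rep$roc$auc_full$auc,
  delong_p = rep$roc$delong$p_value)
#>         base         full     delong_p
#> 6.255679e-01 6.897343e-01 2.110292e-17

rep$concordance
#> $r
#> [1] 0.9858547
#> $n
#> [1] 947
#> $excluded
#> [1] 4184
```

Men in the top PRS quintile have ~4-fold the LOY odds of the bottom
quintile; adding the PRS to age + smoking + alcohol raises the in-sample
AUC from 0.626 to 0.690 (DeLong p ≈ 2e-17); and the array-derived mLRRY
agrees with the WGS read-depth log2 ratio at r = 0.99 in the sequenced
subset of 947 men.

The same analysis runs file-to-file:

```r
cmd_simulate(cfg, "dataset/")          # TSV dataset + manifest.json
cmd_run("dataset/", "results/")        # calls, PRS, models, ROC & concordance reports
```

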