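---
title: "Methods: predicting mosaic loss of chromosome Y from a polygenic score"
author: "loyprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting mosaic loss of chromosome Y from a polygenic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loyprs)
```

## The problem

Mosaic loss of chromosome Y (LOY) is the most common acquired chromosomal
change in the blood of ageing men: a clone of leukocytes loses its single Y
chromosome and may expand over time. LOY in blood is an established marker
of genomic instability, associated with mortality and a range of common
diseases. Germline GWAS have identified on the order of 156 independent
variants predisposing to LOY, which makes a polygenic risk score (PRS) a
natural instrument for identifying men likely to carry LOY before or
alongside direct measurement.

`loyprs` implements the full analysis chain needed to evaluate such a score
in a cohort of older men: calling LOY from SNP-array intensity data,
constructing the PRS from a weight file, modelling the association between
score and LOY status, comparing prediction models by ROC/AUC, and
validating array calls against whole-genome-sequencing (WGS) read depth.
Because the real genotype data such analyses run on are access-controlled,
the package ships a seeded synthetic-cohort generator with known ground
truth, and every stage is tested against that truth.

## LOY from array intensity: the mLRRY statistic

The Log R Ratio (LRR) of a probe is the logged ratio of observed to
expected intensity; a copy-number loss in a fraction of cells depresses the
LRR of probes in the lost region. The per-sample statistic is

$$\mathrm{mLRRY} = \operatorname{median}\{\,\mathrm{LRR}_p : p \in \mathrm{MSY}\,\},$$

the median over the probes of the male-specific region of chromosome Y
(488 probes at the generator defaults, mirroring a standard array). The
median over several hundred probes is robust to single-probe artifacts and
has sampling noise $\approx 1.2533\,\sigma_{\mathrm{probe}}/\sqrt{488}
\approx 0.017$ LRR units at the default probe noise SD of 0.3.

### From mLRRY to percent of affected cells

A sample whose cell fraction $f$ has lost the Y is an intensity mixture of
diploid-Y-null and normal cells, giving an expected MSY shift of
$c\,\log_2(1-f)$ for an array response factor $c \in (0, 1]$. Inverting,

$$f = 1 - 2^{\mathrm{mLRRY}/c}, \qquad c = 0.46 \text{ by default.}$$

The default is calibrated so that the conventional calling threshold
$\mathrm{mLRRY} = -0.06$ corresponds to 8.6% of cells, the operating pair
used in published LOY work on this array class. The exact conversion used
by upstream LOY studies is not public in closed form, so $c$ is an explicit,
configurable parameter recorded in output metadata, not a claimed
reproduction. Positive mLRRY values clamp to 0% (a proportion cannot be
negative); the conversion is strictly decreasing for negative mLRRY.

### The calling threshold: a reflected experimental-error null

LOY can only depress mLRRY, so in a males-only cohort (no female technical
controls) the values at and above the central mode are attributable to
technical noise alone. `estimate_threshold()`:

1. estimates the mode of the mLRRY distribution by Gaussian-kernel density
   estimation restricted to median $\pm$ 3 MAD;
2. reflects the observations at or above the mode to the other side,
   producing a symmetric "experimental error" null;
3. sets the threshold at the lower 0.5th percentile of that null
   (equivalently, the same distance below the mode as the 99.5th percentile
   sits above it).

For Gaussian noise with SD $s$ this converges to $\mathrm{mode} - 2.576\,s$.
Two numerical choices matter. The KDE bandwidth is three times the
Silverman plug-in value, and the discrete argmax is refined by parabolic
interpolation: oversmoothing does not bias the centre of a symmetric peak
but substantially reduces the variance of its location, which otherwise
propagates doubled into the threshold. Second, the reflected quantile uses
the continuous type-8 estimator. A fixed threshold (e.g. the published
$-0.06$) is available through `fixed_threshold()` for replicating a given
operating point. Degenerate input (all values identical) returns that value
with a warning rather than failing.

Binary calls use a strict inequality — a sample exactly at the threshold is
not called — and both the continuous (mLRRY, percent of cells) and binary
variables are retained for modelling.

## The polygenic risk score

The score file is a headered TSV (`variant_id`, `chrom`, `pos`,
`effect_allele`, `other_allele`, `weight`), a PGS-catalog-compatible
subset, with weights in log-odds-ratio units. Construction follows
standard score-tooling semantics:

* **Variant QC.** Call rate strictly above 90% (a variant at exactly 0.90
  fails), Hardy–Weinberg exact p ≥ 1e-6, imputation $r^2 \ge 0.3$ (a
  variant at exactly 0.30 is retained, matching the "remove $r^2 < 0.3$"
  rule). The HWE p-value threshold is not fixed by convention in the
  source analyses; 1e-6 is the usual choice for imputed array data and is
  configurable. The HWE test is the exact conditional test: given the
  allele counts, heterozygote counts are enumerated and probabilities no
  larger than the observed one are summed (two-sided), in log space for
  numerical range.
* **Allele alignment.** Variants are matched by id with a chrom/pos
  cross-check; where the dosage file counts the other allele the dosage is
  replaced by $2-d$; allele-incompatible or unmatched variants are dropped
  and counted. Strand-ambiguous (A/T, C/G) pairs are out of scope — the
  generator never emits them — so no frequency-based strand inference is
  attempted.
* **Score.** $s_i = \sum_v w_v \, d_{iv}$ with missing dosages mean-imputed
  as twice the observed effect-allele frequency (configurable to
  skip-per-sample instead). A sample missing every dosage scores `NA`.
* **Standardisation and risk groups.** Z-scores have cohort mean 0, SD 1.
  Risk groups are rank-based quintile bands — low = bottom 20%, high = top
  20%, middle = the rest — with ties broken by stable input order so the
  groups partition the cohort exactly (1026/3079/1026 at n = 5131).
  Rank-based cuts rather than value quantiles were chosen because the group
  definition is a percentile band, and exact splits should hold under ties.

## Association and prediction models

All models code smoking and alcohol as *current* vs *never/former* (the
pooled reference), keeping the 3-level coding only for descriptive tables.

* `fit_logistic()` wraps the IRLS maximum-likelihood fit with Wald
  inference: OR $= e^{\hat\beta}$, 95% CI $= e^{\hat\beta \pm 1.96\,SE}$.
  Convergence tolerance 1e-8, 25 iterations. Rank deficiency errors naming
  the collinear terms; separation (|coef| > 15 or SE > 100) errors with
  diagnostics instead of returning an unstable fit. Profile-likelihood CIs
  are deliberately out of scope.
* `ancova_prs()` compares PRS distributions by LOY status adjusted for age,
  smoking and alcohol, as the linear model `prs_z ~ loy + covariates`;
  the reported p is the LOY-term p and adjusted means are evaluated at
  covariate means. With no covariates it reduces exactly to the
  pooled-variance two-sample t-test.
* `t_test()` defaults to Welch (the robust default when only "t-test" is
  specified); `wilcoxon_rank_sum()` uses the normal approximation with tie
  correction; `chi_square_test()` is Pearson without continuity correction
  (cohort-scale counts), both configurable.
* `roc_auc()` computes the AUC through the rank/Mann–Whitney identity (ties
  count ½) and its CI from the DeLong structural-component variance.
  `delong_test()` compares two correlated AUCs on the same samples through
  the covariance of those components; identical predictions give p = 1 by
  construction. Models are fit and evaluated in-sample (documented choice;
  no cross-validation), matching how such cohort AUC comparisons are
  usually reported.
* Age-stratified models use left-closed bins [70,75), [75,80), [80,∞) and
  exclude age within strata. A stratum missing an outcome class or a second
  PRS group — or whose fit separates — is reported *unestimable* with the
  reason, never silently dropped. Covariates constant within a stratum
  (e.g. no current smokers among the oldest men in a small cohort) are
  omitted from that stratum's design.

## WGS read-depth validation

In an unaffected male the haploid MSY is expected to have half the
autosomal per-window read depth, so

$$\text{y\_log2\_ratio} = \log_2\!\frac{\overline{\mathrm{MSY}}}{0.5\,\overline{\mathrm{AUT}}},$$

which is 0 without LOY and $\log_2(1-f)$ with cell fraction $f$; the
implied percentage is clamped to [0, 100]. Windows are summarised by the
mean by default (Poisson-simulated windows are outlier-free) with the
median available for real data. GC correction, segmentation and breakpoint
calling of dedicated CNV callers are out of scope: counts are consumed
precomputed. Concordance with the array estimate is the Pearson correlation
of paired log2-scale values over complete pairs.

## The synthetic cohort: what it emulates

`sim_config()` defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 5131 | cohort size of the reference population of men aged 70+ |
| `n_msy_probes` | 488 | MSY probe count of the emulated array |
| `probe_noise_sd` | 0.3 LRR | realistic per-probe noise; yields mLRRY noise ≈ 0.017 |
| `response_factor` | 0.46 | calibrated so −0.06 mLRRY ↔ 8.6% of cells |
| `age_weights` | 0.60/0.25/0.10/0.05 over 70–74/75–79/80–84/85+ | reproduces mean age ≈ 75 and the observed age-prevalence gradient |
| `smoking_probs` | 43.9/52.6/3.5% | reference-cohort mix |
| `alcohol_probs` | 9.0/5.7/85.3% | reference-cohort mix |
| `beta_prs` | ln 1.74 | generating per-SD effect |
| `beta_age` | ln 1.11 per year | generating age effect |
| `beta_smoke`, `beta_alc` | ln 2.13, ln 1.21 | generating exposure effects |
| `beta0` | −1.3463 | solved numerically so overall prevalence is 27.2% under the defaults |
| `fraction_range`, shapes | Beta(1.5, 3) on [0.09, 0.80] | affected men sit above the calling point most of the time; the true fraction law in affected men is unknown, so this is a stand-in, not an inference |
| `qc_fail_share` | 33/156 | so 123 of 156 variants survive default QC |
| `wgs_autosomal_depth` | 30 | 30× coverage; `n_wgs_samples` 947 sequenced subset |

LOY status is drawn from
$\operatorname{logit} P = \beta_0 + \beta_{age}(age-75) + \beta_{prs} z +
\beta_{smoke}\,\mathrm{cur.smoker} + \beta_{alc}\,\mathrm{cur.alcohol}$,
with the true PRS $z$ computed from the QC-clean variants only — the
engineered QC failures model measurement artifacts, so they carry no true
effect and the per-SD generating effect is well-defined against the
measurable score. Genotypes are hard calls in Hardy–Weinberg proportions
emitted as dosages; the engineered failures split across the three filters
(low $r^2$ drawn below 0.3, masked call rate drawn below 0.9, excess
homozygosity with inbreeding-type distortion F = 0.5, the latter given
common alleles so the exact test always has power to flag it). One master
seed drives deterministic per-stage sub-streams, so any stage can be
regenerated independently and identical seeds give identical datasets.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: linkage disequilibrium between variants, raw
intensity artifacts (GC waves, batch effects, plate structure), partial-Y
or other chromosome mosaicism, clonal expansion over time, strand-ambiguous
variants, population stratification, and the survivorship profile of a
healthy-volunteer cohort. Parameter-recovery results show the estimators
are correct under the stated model, not that the model captures every
feature of array data.

## Numerical choices and degenerate inputs

* Medians use the midpoint convention for even counts; samples with no
  usable MSY probe are unscorable (`NA`) and counted, not dropped silently.
* A mosaic fraction of exactly 1 would need $\log_2 0$; the generator
  clamps it to 0.999 with a warning.
* `hwe_exact_test()` normalises the enumerated probabilities and compares
  with a $1+10^{-12}$ relative tolerance to avoid float-order artifacts;
  monomorphic variants return p = 1.
* Zero-variance inputs error explicitly (standardisation, concordance)
  or return the documented degenerate value (t-test p = 1 for two equal
  constant groups, Wilcoxon p = 1 under all-ties, threshold = the common
  value for constant mLRRY).
* DeLong with identical predictions has zero variance of the difference and
  returns z = 0, p = 1 rather than 0/0.

## Problem sizes used in the test suite

The suite exercises the full default conditions where the property being
tested demands them (effect recovery over 20 replicates at n = 5131;
fraction recovery at n = 5000 with 488 probes; DeLong calibration over 2000
null replicates at n = 120; concordance at n = 947) and smaller cohorts
(n = 400) where only mechanics are at stake. The whole suite runs in about
a minute; `scripts/acceptance.R` in a few seconds.

## Known limitations

* The mLRRY→fraction conversion and the empirical-null construction are
  documented conventions calibrated to the published operating pair, not
  reproductions of the (unpublished) upstream implementations.
* The PRS applies no shrinkage, p-value thresholding or LD clumping by
  design; weights are used as given.
* In-sample AUC comparison is optimistic relative to external validation.
* The quintile-contrast OR on synthetic data is sensitive to the assumed
  fraction law and misclassification near the threshold; it is a direction
  check, not a reproduction of any particular cohort's value.
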