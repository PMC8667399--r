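#' Simulation configuration for the synthetic LOY cohort
#'
#' Builds and validates the parameter set that drives the synthetic-data
#' generator. Defaults emulate a cohort of healthy men aged 70 and older:
#' 5131 samples, 488 male-specific Y (MSY) probes, a logistic generative
#' model of LOY status driven by age, polygenic score, smoking and alcohol
#' use, and Poisson WGS read-depth windows at 30x autosomal coverage.
#'
#' The generative log-odds coefficients default to the effect sizes the
#' association layer is expected to recover: an odds ratio of 1.74 per SD of
#' the PRS, 1.11 per year of age, 2.13 for current smoking and 1.21 for
#' current alcohol use, with the intercept placed so that overall LOY
#' prevalence is 27.2% under the default covariate mix.
#'
#' @param n_samples Number of men in the cohort.
#' @param n_variants Number of score variants to simulate.
#' @param n_msy_probes Number of MSY probes on the simulated array.
#' @param n_autosomal_probes Number of autosomal reference probes.
#' @param probe_noise_sd Gaussian noise SD of a single probe's LRR value.
#' @param response_factor Array response factor `c` linking mLRRY to the
#'   fraction of cells with LOY via `f = 1 - 2^(mLRRY / c)`; must be in
#'   (0, 1].
#' @param age_weights Named weights over the age bins `70-74`, `75-79`,
#'   `80-84`, `85+`; must sum to 1.
#' @param smoking_probs,alcohol_probs Named weights over
#'   `never`/`former`/`current`; must each sum to 1.
#' @param bmi_probs Named weights over BMI categories; must sum to 1.
#' @param beta0,beta_age,beta_prs,beta_smoke,beta_alc Log-odds coefficients
#'   of the generative LOY model
#'   `logit(P) = beta0 + beta_age*(age-75) + beta_prs*z + beta_smoke*current_smoker + beta_alc*current_alcohol`.
#' @param fraction_shape1,fraction_shape2 Beta-law shape parameters for the
#'   mosaic fraction of affected men.
#' @param fraction_range Interval of (0,1) onto which the Beta draw is
#'   rescaled; affected men carry fractions inside this range.
#' @param baseline_fraction_sd Half-normal SD of the residual fraction in
#'   unaffected men (0 = exactly zero).
#' @param eaf_range Uniform range of effect-allele frequencies.
#' @param weight_sd SD of the Gaussian log-odds-ratio weights in the score
#'   file.
#' @param qc_fail_share Share of variants engineered to fail default QC
#'   (33/156 by default, so 123 of 156 variants survive).
#' @param missing_rate Genotype missingness of QC-passing variants.
#' @param wgs_autosomal_depth Expected reads per autosomal WGS window.
#' @param n_wgs_msy_windows,n_wgs_auto_windows Window counts per class.
#' @param n_wgs_samples Number of samples with WGS data (a cohort subset).
#' @param seed Master integer seed; per-stage sub-streams are derived from
#'   it deterministically.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 200, n_variants = 20, seed = 7)
#' cov <- generate_cohort(cfg)
#' head(cov)
sim_config <- function(n_samples = 5131,
                       n_variants = 156,
                       n_msy_probes = 488,
                       n_autosomal_probes = 500,
                       probe_noise_sd = 0.3,
                       response_factor = 0.46,
                       age_weights = c("70-74" = 0.60, "75-79" = 0.25,
                                       "80-84" = 0.10, "85+" = 0.05),
                       smoking_probs = c(never = 0.439, former = 0.526,
                                         current = 0.035),
                       alcohol_probs = c(never = 0.090, former = 0.057,
                                         current = 0.853),
                       bmi_probs = c(underweight = 38, normal = 1063,
                                     overweight = 2633, obese = 1298,
                                     missing = 18) / 5050,
                       beta0 = -1.3463,
                       beta_age = log(1.11),
                       beta_prs = log(1.74),
                       beta_smoke = log(2.13),
                       beta_alc = log(1.21),
                       fraction_shape1 = 1.5,
                       fraction_shape2 = 3,
                       fraction_range = c(0.09, 0.80),
                       baseline_fraction_sd = 0,
                       eaf_range = c(0.05, 0.95),
                       weight_sd = 0.10,
                       qc_fail_share = 33 / 156,
                       missing_rate = 0.005,
                       wgs_autosomal_depth = 30,
                       n_wgs_msy_windows = 100,
                       n_wgs_auto_windows = 200,
                       n_wgs_samples = 947,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_msy_probes = as.integer(n_msy_probes),
    n_autosomal_probes = as.integer(n_autosomal_probes),
    probe_noise_sd = probe_noise_sd, response_factor = response_factor,
    age_weights = age_weights, smoking_probs = smoking_probs,
    alcohol_probs = alcohol_probs, bmi_probs = bmi_probs,
    beta0 = beta0, beta_age = beta_age, beta_prs = beta_prs,
    beta_smoke = beta_smoke, beta_alc = beta_alc,
    fraction_shape1 = fraction_shape1, fraction_shape2 = fraction_shape2,
    fraction_range = fraction_range,
    baseline_fraction_sd = baseline_fraction_sd,
    eaf_range = eaf_range, weight_sd = weight_sd,
    qc_fail_share = qc_fail_share, missing_rate = missing_rate,
    wgs_autosomal_depth = wgs_autosomal_depth,
    n_wgs_msy_windows = as.integer(n_wgs_msy_windows),
    n_wgs_auto_windows = as.integer(n_wgs_auto_windows),
    n_wgs_samples = as.integer(n_wgs_samples),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 0, cfg$n_variants >= 0)
  if (cfg$n_msy_probes < 1) {
    stop("configuration error: n_msy_probes must be >= 1", call. = FALSE)
  }
  if (!is.finite(cfg$probe_noise_sd) || cfg$probe_noise_sd <= 0) {
    stop("configuration error: probe_noise_sd must be > 0", call. = FALSE)
  }
  if (cfg$response_factor <= 0 || cfg$response_factor > 1) {
    stop("configuration error: response_factor must be in (0, 1]",
         call. = FALSE)
  }
  for (nm in c("age_weights", "smoking_probs", "alcohol_probs", "bmi_probs")) {
    w <- cfg[[nm]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
      stop(sprintf("configuration error: %s must be non-negative and sum to 1",
                   nm), call. = FALSE)
    }
  }
  if (cfg$fraction_range[1] <= 0 || cfg$fraction_range[2] >= 1 ||
      cfg$fraction_range[1] >= cfg$fraction_range[2]) {
    stop("configuration error: fraction_range must be an interval inside (0,1)",
         call. = FALSE)
  }
  if (cfg$wgs_autosomal_depth <= 0) {
    stop("configuration error: wgs_autosomal_depth must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic per-stage sub-seed so stages can be regenerated independently
# from one master seed. Kept strictly below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 1L, genotypes = 2L, true_loy = 3L, lrr = 4L,
               wgs = 5L, analysis = 6L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]] * 1000003) %% 2147483629)
}
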