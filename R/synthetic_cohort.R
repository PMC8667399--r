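#' Generate the covariate table of a synthetic cohort
#'
#' Draws one row per man: age (sampled within an age bin chosen by the
#' configured bin weights), smoking and alcohol status, a 50/50 randomised
#' treatment assignment, and a BMI category. Ages within the top bin (85+)
#' are drawn uniformly on \[85, 93).
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `sample_id`, `age`, `age_bin`,
#'   `smoking`, `alcohol`, `treatment`, `bmi_category`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "cohort"))
  n <- config$n_samples
  if (n == 0) {
    return(data.frame(sample_id = character(), age = numeric(),
                      age_bin = character(), smoking = character(),
                      alcohol = character(), treatment = character(),
                      bmi_category = character(),
                      stringsAsFactors = FALSE))
  }
  bin_lo <- c(70, 75, 80, 85)
  bin_hi <- c(75, 80, 85, 93)
  bin <- sample.int(4L, n, replace = TRUE, prob = config$age_weights)
  age <- runif(n, bin_lo[bin], bin_hi[bin])
  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    age = age,
    age_bin = names(config$age_weights)[bin],
    smoking = sample(names(config$smoking_probs), n, replace = TRUE,
                     prob = config$smoking_probs),
    alcohol = sample(names(config$alcohol_probs), n, replace = TRUE,
                     prob = config$alcohol_probs),
    treatment = sample(c("placebo", "aspirin"), n, replace = TRUE),
    bmi_category = sample(names(config$bmi_probs), n, replace = TRUE,
                          prob = config$bmi_probs),
    stringsAsFactors = FALSE
  )
}

# Non-strand-ambiguous allele pairs only (no A/T, no C/G), so allele
# alignment between score file and dosage file is always unambiguous.
.allele_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)

#' Generate genotype dosages and a matching variant score file
#'
#' Effect-allele frequencies are uniform on `config$eaf_range`; hard
#' genotypes are drawn in Hardy-Weinberg proportions and emitted as dosages
#' in \[0, 2\]. A configured share of variants is engineered to fail default
#' QC, split across the three filters: low imputation r2 (drawn below 0.3),
#' low call rate (genotypes masked so the observed rate falls below 90%),
#' and Hardy-Weinberg violation (excess homozygosity, inbreeding-type
#' distortion with F = 0.5). The dosage file counts either the effect or
#' the other allele at random, so downstream allele alignment is exercised.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `dosages`: samples x variants matrix of counted-allele dosages
#'     (NA = missing genotype),
#'   * `meta`: per-variant data.frame (`variant_id`, `chrom`, `pos`,
#'     `counted_allele`, `other_allele`, `call_rate`, `hwe_p`,
#'     `imputation_r2`),
#'   * `score`: the score file as a data.frame (`variant_id`, `chrom`,
#'     `pos`, `effect_allele`, `other_allele`, `weight`),
#'   * `truth`: per-variant ground truth (`eaf`, `weight`, `qc_fail_type`,
#'     and the complete unmasked effect-allele count matrix `genotypes`).
#' @export
generate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_samples
  m <- config$n_variants
  stopifnot(m >= 1)
  sample_ids <- sprintf("S%05d", seq_len(n))
  variant_ids <- sprintf("rs%07d", sort(sample.int(9999999L, m)))

  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                        drop = FALSE]
  effect_allele <- pair[, 1]
  other_allele <- pair[, 2]
  chrom <- sample(1:22, m, replace = TRUE)
  pos <- sample.int(2e8L, m, replace = TRUE)
  weight <- rnorm(m, 0, config$weight_sd)

  n_fail <- round(config$qc_fail_share * m)
  fail_idx <- if (n_fail > 0) sample.int(m, n_fail) else integer()
  qc_fail_type <- rep("none", m)
  if (n_fail > 0) {
    types <- rep(c("r2", "call_rate", "hwe"),
                 c(ceiling(n_fail * 0.6),
                   floor(n_fail * 0.2),
                   n_fail - ceiling(n_fail * 0.6) - floor(n_fail * 0.2)))
    qc_fail_type[fail_idx] <- sample(types)
  }

  eaf <- runif(m, config$eaf_range[1], config$eaf_range[2])
  # HWE-violating variants need common alleles so the exact test has the
  # power to flag them at any realistic cohort size.
  hwe_fail <- qc_fail_type == "hwe"
  eaf[hwe_fail] <- runif(sum(hwe_fail), 0.2, 0.8)

  geno <- matrix(0L, n, m, dimnames = list(sample_ids, variant_ids))
  for (j in seq_len(m)) {
    p <- eaf[j]
    if (hwe_fail[j]) {
      f_in <- 0.5  # excess homozygosity
      probs <- c((1 - p)^2 + f_in * p * (1 - p),
                 2 * p * (1 - p) * (1 - f_in),
                 p^2 + f_in * p * (1 - p))
      geno[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
    } else {
      geno[, j] <- rbinom(n, 2L, p)
    }
  }

  # Dosage file counts effect or other allele at random.
  counted_is_effect <- runif(m) < 0.5
  dos <- geno
  dos[, !counted_is_effect] <- 2L - dos[, !counted_is_effect, drop = FALSE]

  miss_rate <- rep(config$missing_rate, m)
  cr_fail <- qc_fail_type == "call_rate"
  miss_rate[cr_fail] <- 1 - runif(sum(cr_fail), 0.60, 0.87)
  dos <- apply_missingness(dos, miss_rate)

  r2 <- runif(m, 0.35, 1)
  r2[qc_fail_type == "r2"] <- runif(sum(qc_fail_type == "r2"), 0.05, 0.295)

  counts <- genotype_counts(dos)
  hwe_p <- vapply(seq_len(m), function(j) {
    hwe_exact_test(counts[j, 1], counts[j, 2], counts[j, 3])
  }, numeric(1))

  meta <- data.frame(
    variant_id = variant_ids, chrom = chrom, pos = pos,
    counted_allele = ifelse(counted_is_effect, effect_allele, other_allele),
    other_allele = ifelse(counted_is_effect, other_allele, effect_allele),
    call_rate = colMeans(!is.na(dos)),
    hwe_p = hwe_p,
    imputation_r2 = r2,
    stringsAsFactors = FALSE
  )
  score <- data.frame(
    variant_id = variant_ids, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    weight = weight, stringsAsFactors = FALSE
  )
  truth <- list(eaf = eaf, weight = weight, qc_fail_type = qc_fail_type,
                genotypes = geno)
  list(dosages = dos, meta = meta, score = score, truth = truth)
}

apply_missingness <- function(dos, miss_rate) {
  storage.mode(dos) <- "double"
  for (j in seq_along(miss_rate)) {
    if (miss_rate[j] > 0) {
      dos[runif(nrow(dos)) < miss_rate[j], j] <- NA_real_
    }
  }
  dos
}

# Hard-call genotype counts (hom-other, het, hom-counted) per variant.
genotype_counts <- function(dos) {
  t(apply(dos, 2, function(d) {
    d <- d[!is.na(d)]
    c(sum(d == 0), sum(d == 1), sum(d == 2))
  }))
}

#' Draw the true LOY state of each man from the generative logistic model
#'
#' LOY status follows
#' `logit(P) = beta0 + beta_age*(age - 75) + beta_prs*z + beta_smoke*current_smoker + beta_alc*current_alcohol`.
#' Affected men receive a mosaic fraction drawn from a Beta law rescaled to
#' `config$fraction_range`; unaffected men sit at (or, with configured
#' jitter, near) zero.
#'
#' @param covariates Output of [generate_cohort()].
#' @param true_prs Z-standardised true polygenic score, one value per row of
#'   `covariates`.
#' @param config A [sim_config()].
#' @return A data.frame (`sample_id`, `true_prob`, `true_loy`,
#'   `true_fraction`).
#' @export
generate_true_loy <- function(covariates, true_prs, config) {
  validate_sim_config(config)
  stopifnot(length(true_prs) == nrow(covariates))
  set.seed(stage_seed(config$seed, "true_loy"))
  lp <- config$beta0 +
    config$beta_age * (covariates$age - 75) +
    config$beta_prs * true_prs +
    config$beta_smoke * (covariates$smoking == "current") +
    config$beta_alc * (covariates$alcohol == "current")
  p <- plogis(lp)
  loy <- rbinom(nrow(covariates), 1L, p)
  frac <- numeric(nrow(covariates))
  n_loy <- sum(loy)
  if (n_loy > 0) {
    u <- rbeta(n_loy, config$fraction_shape1, config$fraction_shape2)
    frac[loy == 1L] <- config$fraction_range[1] +
      u * diff(config$fraction_range)
  }
  if (config$baseline_fraction_sd > 0) {
    jitter <- abs(rnorm(sum(loy == 0L), 0, config$baseline_fraction_sd))
    frac[loy == 0L] <- pmin(jitter, config$fraction_range[1] / 2)
  }
  data.frame(sample_id = covariates$sample_id, true_prob = p,
             true_loy = loy, true_fraction = frac,
             stringsAsFactors = FALSE)
}

#' Simulate a probe-level Log R Ratio matrix
#'
#' Each MSY probe of a sample with mosaic fraction `f` has expected LRR
#' `response_factor * log2(1 - f)` plus Gaussian noise; autosomal reference
#' probes are centred at 0 under the same noise law. A fraction of exactly 1
#' would put the expectation at `log2(0)`; such fractions are clamped to
#' 0.999 with a warning.
#'
#' @param true_state Output of [generate_true_loy()].
#' @param config A [sim_config()].
#' @return A list with `lrr` (probes x samples matrix) and `annotation`
#'   (BED-style data.frame: `chrom`, `start` (0-based), `end`, `probe_id`,
#'   `is_msy`).
#' @export
generate_lrr_matrix <- function(true_state, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "lrr"))
  f <- true_state$true_fraction
  stopifnot(all(f >= 0 & f <= 1))
  if (any(f == 1)) {
    warning("mosaic fraction of exactly 1 clamped to 0.999 for LRR simulation")
    f[f == 1] <- 0.999
  }
  n <- length(f)
  n_msy <- config$n_msy_probes
  n_auto <- config$n_autosomal_probes
  msy_mean <- config$response_factor * log2(1 - f)
  lrr <- matrix(rnorm(as.numeric(n_msy + n_auto) * n, sd = config$probe_noise_sd),
                nrow = n_msy + n_auto, ncol = n)
  if (n > 0) {
    lrr[seq_len(n_msy), ] <- lrr[seq_len(n_msy), , drop = FALSE] +
      rep(msy_mean, each = n_msy)
  }
  probe_id <- c(sprintf("MSY_%04d", seq_len(n_msy)),
                sprintf("AUT_%04d", seq_len(n_auto)))
  dimnames(lrr) <- list(probe_id, true_state$sample_id)
  annotation <- data.frame(
    chrom = c(rep("chrY", n_msy), rep("chr1", n_auto)),
    start = c(2650000 + 10000 * (seq_len(n_msy) - 1),
              1000000 + 10000 * (seq_len(n_auto) - 1)),
    probe_id = probe_id,
    is_msy = c(rep(TRUE, n_msy), rep(FALSE, n_auto)),
    stringsAsFactors = FALSE
  )
  annotation$end <- annotation$start + 1L
  annotation <- annotation[, c("chrom", "start", "end", "probe_id", "is_msy")]
  list(lrr = lrr, annotation = annotation)
}

#' Simulate WGS read-depth windows
#'
#' Autosomal window counts are Poisson with mean `wgs_autosomal_depth`; MSY
#' window counts are Poisson with mean `depth * (1 - f) / 2`, reflecting the
#' single Y chromosome per diploid genome. Only the first
#' `config$n_wgs_samples` samples receive WGS data, emulating a sequenced
#' sub-cohort.
#'
#' @param true_state Output of [generate_true_loy()].
#' @param config A [sim_config()].
#' @return A data.frame (`sample_id`, `chrom`, `start`, `end`, `region`,
#'   `read_count`), windows BED-style 0-based half-open.
#' @export
generate_wgs_depth <- function(true_state, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "wgs"))
  n_wgs <- min(config$n_wgs_samples, nrow(true_state))
  if (n_wgs == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), region = character(),
                      read_count = integer(), stringsAsFactors = FALSE))
  }
  idx <- seq_len(n_wgs)
  lambda <- config$wgs_autosomal_depth
  n_msy <- config$n_wgs_msy_windows
  n_auto <- config$n_wgs_auto_windows
  win <- 10000L
  per_sample <- function(i) {
    f <- true_state$true_fraction[i]
    data.frame(
      sample_id = true_state$sample_id[i],
      chrom = c(rep("chrY", n_msy), rep("chr2", n_auto)),
      start = c(win * (seq_len(n_msy) - 1), win * (seq_len(n_auto) - 1)),
      region = c(rep("MSY", n_msy), rep("autosomal", n_auto)),
      read_count = c(rpois(n_msy, lambda * (1 - f) / 2),
                     rpois(n_auto, lambda)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(idx, per_sample))
  out$end <- out$start + win
  out[, c("sample_id", "chrom", "start", "end", "region", "read_count")]
}

#' Simulate a complete synthetic LOY dataset
#'
#' Runs the full generative chain: cohort covariates, genotypes and score
#' file, true polygenic score (the weighted sum of effect-allele counts over
#' the QC-clean variants, Z-standardised within the cohort), true LOY state,
#' probe-level LRR matrix and WGS depth windows. Each stage draws from its
#' own deterministic sub-stream of the master seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `loy_dataset` with elements `config`,
#'   `covariates`, `genotypes`, `true_state`, `lrr`, `wgs_depth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  covariates <- generate_cohort(config)
  genotypes <- generate_genotypes(config)
  # The generative polygenic effect is attached to the QC-clean variants:
  # the engineered QC failures model measurement artifacts, so they carry
  # no weight in the true score.
  clean <- genotypes$truth$qc_fail_type == "none"
  raw <- as.vector(genotypes$truth$genotypes[, clean, drop = FALSE] %*%
                     genotypes$truth$weight[clean])
  true_prs <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else raw * 0
  true_state <- generate_true_loy(covariates, true_prs, config)
  true_state$true_prs <- true_prs
  lrr <- generate_lrr_matrix(true_state, config)
  wgs_depth <- generate_wgs_depth(true_state, config)
  structure(list(config = config, covariates = covariates,
                 genotypes = genotypes, true_state = true_state,
                 lrr = lrr, wgs_depth = wgs_depth),
            class = "loy_dataset")
}
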