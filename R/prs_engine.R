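#' Read a variant score file
#'
#' Parses a headered TSV of score variants (a PGS-catalog-compatible
#' subset): `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `weight`, the weight being a GWAS log odds ratio. Rows with missing
#' fields, non-finite weights or identical alleles are rejected with the
#' offending line number; duplicate variant ids are an error.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated score variants.
#' @export
read_score_file <- function(path) {
  required <- c("variant_id", "effect_allele", "other_allele", "weight")
  sv <- read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(sv))
  if (length(missing_cols) > 0) {
    stop("score file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(sv) == 0) return(sv)
  # line numbers in the file: header is line 1
  line_no <- seq_len(nrow(sv)) + 1L
  bad <- !is.finite(sv$weight) | is.na(sv$variant_id) |
    sv$variant_id == "" | is.na(sv$effect_allele) | is.na(sv$other_allele)
  if (any(bad)) {
    stop("malformed score file row at line ", line_no[which(bad)[1]],
         call. = FALSE)
  }
  same <- toupper(sv$effect_allele) == toupper(sv$other_allele)
  if (any(same)) {
    stop("effect and other allele identical at line ", line_no[which(same)[1]],
         call. = FALSE)
  }
  dup <- duplicated(sv$variant_id)
  if (any(dup)) {
    stop("duplicate variant_id in score file: ", sv$variant_id[which(dup)[1]],
         call. = FALSE)
  }
  sv
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the probability of observing
#' `h` heterozygotes among `n` diploid genotypes is
#' `P(h) = 2^h * n! / (a! h! b!) / C(2n, nA)` where `a` and `b` are the two
#' homozygote counts and `nA` the minor-allele count. The two-sided exact
#' p-value sums the probabilities of every heterozygote count (of the
#' correct parity) whose probability does not exceed that of the observed
#' configuration. Monomorphic variants return p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total at
#'   least 1).
#' @return Two-sided exact p-value.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)  # perfect proportions: p = 1
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("total genotype count must be at least 1", call. = FALSE)
  n_a <- 2 * n_hom_ref + n_het
  n_b <- 2 * n_hom_alt + n_het
  if (n_a == 0 || n_b == 0) return(1)
  n_minor <- min(n_a, n_b)
  # possible heterozygote counts share the parity of the minor allele count
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  log_p <- hs * log(2) + lgamma(n + 1) -
    lgamma((n_a - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((n_b - hs) / 2 + 1) -
    (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(n_b + 1))
  p <- exp(log_p)
  p <- p / sum(p)  # guard against rounding drift
  p_obs <- p[match(n_het, hs)]
  if (is.na(p_obs)) stop("inconsistent genotype counts", call. = FALSE)
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Applies the three standard post-imputation filters: genotyping call rate
#' strictly above `call_rate_min` (a variant at exactly 90% fails the
#' "> 90%" rule), Hardy-Weinberg exact p at or above `hwe_p_min`, and
#' imputation r2 at or above `r2_min` (the rule removes `r2 < 0.3`, so a
#' variant at exactly 0.30 is retained).
#'
#' @param meta Per-variant data.frame with `variant_id`, `call_rate`,
#'   `hwe_p`, `imputation_r2`.
#' @param call_rate_min Call-rate threshold (strict, default 0.90).
#' @param hwe_p_min HWE p-value threshold (default 1e-6, the convention for
#'   imputed array data).
#' @param r2_min Imputation-quality threshold (default 0.30).
#' @return `meta` with a logical `qc_pass` column added; attribute
#'   `qc_report` holds per-filter exclusion counts.
#' @export
variant_qc <- function(meta, call_rate_min = 0.90, hwe_p_min = 1e-6,
                       r2_min = 0.30) {
  stopifnot(all(c("variant_id", "call_rate", "hwe_p", "imputation_r2") %in%
                  names(meta)))
  fail_cr <- !(meta$call_rate > call_rate_min)
  fail_hwe <- meta$hwe_p < hwe_p_min
  fail_r2 <- meta$imputation_r2 < r2_min
  meta$qc_pass <- !(fail_cr | fail_hwe | fail_r2)
  attr(meta, "qc_report") <- data.frame(
    filter = c("call_rate", "hwe", "imputation_r2", "any"),
    threshold = c(sprintf("> %g", call_rate_min),
                  sprintf(">= %g", hwe_p_min),
                  sprintf(">= %g", r2_min), ""),
    n_failed = c(sum(fail_cr), sum(fail_hwe), sum(fail_r2),
                 sum(!meta$qc_pass)),
    stringsAsFactors = FALSE
  )
  meta
}

#' Align score-file weights to the dosage file's counted alleles
#'
#' Variants are matched by id, with a chromosome/position cross-check when
#' both sides carry coordinates. Where the dosage file counts the effect
#' allele the dosage is used as-is; where it counts the other allele the
#' effective dosage is `2 - dosage`; variants whose alleles are incompatible
#' with the score file, or unmatched ids, are dropped and counted.
#'
#' @param score_variants Data.frame from [read_score_file()].
#' @param dosage_meta Per-variant data.frame of the dosage file with
#'   `variant_id`, `counted_allele`, `other_allele` and optionally
#'   `chrom`/`pos`.
#' @return A data.frame (`variant_id`, `weight`, `flip` — TRUE where the
#'   dosage must be replaced by `2 - dosage`); attribute `dropped` reports
#'   counts by reason.
#' @export
align_alleles <- function(score_variants, dosage_meta) {
  m <- match(score_variants$variant_id, dosage_meta$variant_id)
  unmatched <- is.na(m)
  sv <- score_variants[!unmatched, , drop = FALSE]
  dm <- dosage_meta[m[!unmatched], , drop = FALSE]

  pos_mismatch <- rep(FALSE, nrow(sv))
  if (all(c("chrom", "pos") %in% names(sv)) &&
      all(c("chrom", "pos") %in% names(dm))) {
    pos_mismatch <- sv$chrom != dm$chrom | sv$pos != dm$pos
    if (any(pos_mismatch)) {
      warning(sum(pos_mismatch),
              " variant(s) matched by id but mismatched on chrom/pos: dropped")
    }
  }
  as_is <- dm$counted_allele == sv$effect_allele &
    dm$other_allele == sv$other_allele
  flipped <- dm$counted_allele == sv$other_allele &
    dm$other_allele == sv$effect_allele
  incompatible <- !(as_is | flipped)
  keep <- !pos_mismatch & !incompatible
  out <- data.frame(variant_id = sv$variant_id[keep],
                    weight = sv$weight[keep],
                    flip = flipped[keep], stringsAsFactors = FALSE)
  attr(out, "dropped") <- c(unmatched = sum(unmatched),
                            pos_mismatch = sum(pos_mismatch),
                            allele_incompatible = sum(incompatible & !pos_mismatch))
  out
}

#' Polygenic score as a weighted dosage sum
#'
#' `raw_score(sample) = sum_v weight_v * effect_dosage_v(sample)`, the
#' effect dosage being the counted dosage, or `2 - dosage` for flipped
#' variants. Missing dosages are mean-imputed as twice the effect-allele
#' frequency observed in the cohort (the convention of common score-file
#' tooling), unless `impute_missing = FALSE`, in which case the variant is
#' skipped for that sample. A sample missing every dosage scores NA.
#'
#' @param dosages Samples x variants matrix of counted-allele dosages.
#' @param aligned Output of [align_alleles()].
#' @param impute_missing Mean-impute missing dosages (default TRUE).
#' @return Named numeric vector of raw scores.
#' @export
compute_prs <- function(dosages, aligned, impute_missing = TRUE) {
  stopifnot(all(aligned$variant_id %in% colnames(dosages)))
  d <- dosages[, aligned$variant_id, drop = FALSE]
  if (any(aligned$flip)) {
    d[, aligned$flip] <- 2 - d[, aligned$flip, drop = FALSE]
  }
  all_missing <- rowSums(!is.na(d)) == 0
  if (impute_missing) {
    eff_freq <- colMeans(d, na.rm = TRUE) / 2
    for (j in seq_len(ncol(d))) {
      d[is.na(d[, j]), j] <- 2 * eff_freq[j]
    }
    score <- as.vector(d %*% aligned$weight)
  } else {
    w <- matrix(aligned$weight, nrow(d), ncol(d), byrow = TRUE)
    w[is.na(d)] <- 0
    d[is.na(d)] <- 0
    score <- rowSums(d * w)
  }
  score[all_missing] <- NA_real_
  setNames(score, rownames(dosages))
}

#' Z-standardise scores and assign quintile risk groups
#'
#' Scores are standardised to cohort mean 0 and SD 1. Risk groups follow
#' rank-based quintile bands: the lowest 20% of ranks (`floor(n/5)` samples)
#' are `low`, the top `floor(n/5)` are `high`, and the remainder `middle`.
#' Ties are broken by stable input order, so the three groups always
#' partition the cohort exactly (1026 / 3079 / 1026 at n = 5131).
#'
#' @param raw_scores Named numeric vector of raw scores (NAs allowed; at
#'   least 5 non-missing values required).
#' @return A data.frame (`sample_id`, `raw_score`, `z_score`, `risk_group`)
#'   with `risk_group` a factor levelled `low < middle < high`.
#' @export
standardize_and_group <- function(raw_scores) {
  ok <- !is.na(raw_scores)
  if (sum(ok) < 5) stop("need at least 5 non-missing scores", call. = FALSE)
  mu <- mean(raw_scores[ok])
  s <- sd(raw_scores[ok])
  if (s == 0) stop("zero variance: scores cannot be standardised",
                   call. = FALSE)
  z <- (raw_scores - mu) / s
  n <- sum(ok)
  n_tail <- floor(n / 5)
  r <- rank(raw_scores[ok], ties.method = "first")
  grp <- rep("middle", n)
  grp[r <= n_tail] <- "low"
  grp[r > n - n_tail] <- "high"
  group <- rep(NA_character_, length(raw_scores))
  group[ok] <- grp
  ids <- names(raw_scores)
  if (is.null(ids)) ids <- as.character(seq_along(raw_scores))
  data.frame(sample_id = ids, raw_score = unname(raw_scores),
             z_score = unname(z),
             risk_group = factor(group, levels = c("low", "middle", "high")),
             stringsAsFactors = FALSE)
}
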