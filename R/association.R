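#' Logistic regression association model
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) with Wald inference: odds ratio `exp(coef)` and 95%
#' confidence interval `exp(coef +/- 1.96 * SE)` per term. Rank-deficient
#' designs are an error naming the collinear terms; separation or
#' non-convergence is an error with diagnostics rather than a silently
#' unstable fit.
#'
#' @param formula Model formula; the outcome must be binary (0/1).
#' @param data Data.frame holding the variables.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A data.frame of class `assoc_result` (`term`, `estimate`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`), with attributes `n`,
#'   `converged`, `iterations`.
#' @export
fit_logistic <- function(formula, data, conf_level = 0.95) {
  outcome <- model.response(model.frame(formula, data))
  if (!all(outcome %in% c(0, 1))) {
    stop("outcome must be binary (0/1)", call. = FALSE)
  }
  # diagnostics below replace glm's own 0/1-fitted-probability warnings
  fit <- suppressWarnings(glm(formula, data = data, family = binomial(),
                              control = list(epsilon = 1e-8, maxit = 25)))
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(vcov(fit)))
  if (!fit$converged || any(abs(cf) > 15) || any(se > 100)) {
    stop(sprintf(paste0("logistic fit unstable (converged = %s, max |coef| = ",
                        "%.2f, max SE = %.2f); possible separation"),
                 fit$converged, max(abs(cf)), max(se)), call. = FALSE)
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    term = names(cf), estimate = unname(cf), se = unname(se),
    odds_ratio = exp(unname(cf)),
    ci_low = exp(unname(cf - zq * se)), ci_high = exp(unname(cf + zq * se)),
    p_value = 2 * pnorm(-abs(unname(cf) / unname(se))),
    stringsAsFactors = FALSE
  )
  structure(out, n = nrow(model.frame(formula, data)),
            converged = fit$converged, iterations = fit$iter,
            class = c("assoc_result", "data.frame"))
}

#' Linear regression association model
#'
#' Ordinary least squares with t-based p-values and confidence intervals,
#' for continuous outcomes such as mLRRY or the PRS itself.
#'
#' @inheritParams fit_logistic
#' @return A data.frame of class `assoc_result` (`term`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p_value`) with attributes `n`, `df_residual`.
#' @export
fit_linear <- function(formula, data, conf_level = 0.95) {
  fit <- lm(formula, data = data)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  tq <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  out <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    ci_low = sm[, 1] - tq * sm[, 2], ci_high = sm[, 1] + tq * sm[, 2],
    p_value = sm[, 4], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, n = nrow(model.frame(formula, data)),
            df_residual = fit$df.residual,
            class = c("assoc_result", "data.frame"))
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Association model (n = %s)\n", attr(x, "n")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Current-exposure indicator
#'
#' Models code smoking and alcohol as current vs never/former (the
#' never/former pool is the reference); the full 3-level coding is kept for
#' descriptive tables only.
#'
#' @param x Character vector with values in never/former/current.
#' @return Integer 0/1 indicator of current exposure.
#' @export
encode_current <- function(x) as.integer(x == "current")

#' ANCOVA comparison of PRS distributions by LOY status
#'
#' Tests whether the mean standardised PRS differs between men with and
#' without LOY after adjusting for age, smoking and alcohol use. Implemented
#' as the linear model `prs_z ~ loy + age + current_smoker + current_alcohol`;
#' the reported p-value is the LOY-term p, and the adjusted group means are
#' evaluated at the covariate means. With `covariates = NULL` the model
#' reduces to `prs_z ~ loy`, i.e. a pooled-variance two-sample comparison.
#'
#' @param prs_z Standardised PRS vector.
#' @param loy_binary 0/1 LOY status vector, aligned with `prs_z`.
#' @param covariates Optional data.frame with `age`, `smoking`, `alcohol`
#'   aligned with `prs_z`.
#' @return A list (`p_value`, `adjusted_means` (named `no`/`yes`),
#'   `estimate` (adjusted difference), `fit`).
#' @export
ancova_prs <- function(prs_z, loy_binary, covariates = NULL) {
  stopifnot(length(prs_z) == length(loy_binary))
  d <- data.frame(prs_z = prs_z, loy = loy_binary)
  if (is.null(covariates)) {
    fit <- fit_linear(prs_z ~ loy, d)
    base <- fit$estimate[fit$term == "(Intercept)"]
  } else {
    stopifnot(nrow(covariates) == length(prs_z))
    d$age <- covariates$age
    d$current_smoker <- encode_current(covariates$smoking)
    d$current_alcohol <- encode_current(covariates$alcohol)
    fit <- fit_linear(prs_z ~ loy + age + current_smoker + current_alcohol, d)
    cf <- setNames(fit$estimate, fit$term)
    base <- cf[["(Intercept)"]] + cf[["age"]] * mean(d$age) +
      cf[["current_smoker"]] * mean(d$current_smoker) +
      cf[["current_alcohol"]] * mean(d$current_alcohol)
  }
  b_loy <- fit$estimate[fit$term == "loy"]
  list(p_value = fit$p_value[fit$term == "loy"],
       adjusted_means = c(no = unname(base), yes = unname(base + b_loy)),
       estimate = unname(b_loy), fit = fit)
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson statistic without continuity correction (the default here, since
#' cohort-scale counts are large), df = (r-1)(c-1), upper-tail p. A zero row
#' or column margin is an error.
#'
#' @param contingency Matrix of non-negative counts, at least 2x2.
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return A list (`statistic`, `df`, `p_value`, `expected`).
#' @export
chi_square_test <- function(contingency, correct = FALSE) {
  contingency <- as.matrix(contingency)
  stopifnot(nrow(contingency) >= 2, ncol(contingency) >= 2,
            all(contingency >= 0))
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("zero row or column margin: chi-square test undefined", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(contingency, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Two-sample t-test
#'
#' Welch's unequal-variance form by default (`var_equal = TRUE` gives the
#' pooled form). Two degenerate constant groups with equal means return
#' p = 1.
#'
#' @param group_a,group_b Numeric vectors with at least 2 observations each.
#' @param var_equal Pool the variances.
#' @return A list (`statistic`, `df`, `p_value`, `mean_a`, `mean_b`).
#' @export
t_test <- function(group_a, group_b, var_equal = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    same <- mean(group_a) == mean(group_b)
    return(list(statistic = if (same) 0 else Inf, df = NA_real_,
                p_value = if (same) 1 else 0,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Wilcoxon rank-sum test
#'
#' Normal approximation with tie correction. Two groups whose pooled values
#' are all identical return the null-centred statistic and p = 1.
#'
#' @param group_a,group_b Numeric vectors with at least 2 observations each.
#' @return A list (`statistic` (Mann-Whitney U of `group_a`), `p_value`).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (length(unique(c(group_a, group_b))) == 1) {
    return(list(statistic = length(group_a) * length(group_b) / 2,
                p_value = 1))
  }
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Baseline characteristics table by LOY status
#'
#' Summarises age (mean, SD; Welch t-test between LOY groups) and the
#' categorical baseline variables (counts with column percentages to one
#' decimal; Pearson chi-square test), in the three columns all / LOY-no /
#' LOY-yes. Empty categories are retained with count 0. Percentages are
#' always recomputed from the counts and the column denominator.
#'
#' @param covariates Data.frame with `sample_id`, `age` and the categorical
#'   variables.
#' @param loy_calls Data.frame with `sample_id` and `is_loy`.
#' @param categorical Names of the categorical covariate columns.
#' @return A list: `age` (means, SDs, p), `categorical` (one data.frame per
#'   variable: level, counts, percentages, attribute `p_value`).
#' @export
baseline_table <- function(covariates, loy_calls,
                           categorical = c("smoking", "alcohol", "treatment",
                                           "bmi_category")) {
  d <- merge(covariates, loy_calls[, c("sample_id", "is_loy")],
             by = "sample_id")
  d <- d[!is.na(d$is_loy), ]
  grp_no <- d$is_loy == 0
  age <- list(
    mean_all = mean(d$age), sd_all = sd(d$age),
    mean_no = mean(d$age[grp_no]), sd_no = sd(d$age[grp_no]),
    mean_yes = mean(d$age[!grp_no]), sd_yes = sd(d$age[!grp_no]),
    p_value = t_test(d$age[grp_no], d$age[!grp_no])$p_value
  )
  cat_tabs <- lapply(categorical, function(v) {
    lev <- sort(unique(d[[v]]))
    tab <- table(factor(d[[v]], levels = lev), d$is_loy)
    counts_all <- rowSums(tab)
    out <- data.frame(
      level = lev,
      n_all = as.integer(counts_all),
      pct_all = round(100 * counts_all / nrow(d), 1),
      n_no = as.integer(tab[, "0"]),
      pct_no = round(100 * tab[, "0"] / sum(grp_no), 1),
      n_yes = as.integer(tab[, "1"]),
      pct_yes = round(100 * tab[, "1"] / sum(!grp_no), 1),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    nz <- rowSums(tab) > 0
    attr(out, "p_value") <- if (sum(nz) >= 2) {
      chi_square_test(tab[nz, , drop = FALSE])$p_value
    } else NA_real_
    out
  })
  names(cat_tabs) <- categorical
  list(age = age, categorical = cat_tabs, n = nrow(d),
       n_no = sum(grp_no), n_yes = sum(!grp_no))
}

#' Verify printed column percentages of a reference baseline table
#'
#' Recomputes one-decimal column percentages from printed counts and a
#' column denominator and flags cells whose printed percentage does not
#' match. Useful for auditing published cohort tables whose percentage
#' denominators are not the stated column totals (a common artefact when a
#' variable with its own missingness is tabulated against the full-cohort
#' denominator). A copy of such a reference table for a cohort of 5131
#' older men ships as
#' `system.file("extdata", "published_baseline_counts.tsv", package = "loyprs")`.
#'
#' @param counts Integer vector of printed category counts.
#' @param printed_pct Printed one-decimal percentages, aligned with
#'   `counts`.
#' @param denominator Column total the percentages should refer to.
#' @return A data.frame (`count`, `printed_pct`, `recomputed_pct`,
#'   `consistent`).
#' @export
verify_table_percentages <- function(counts, printed_pct, denominator) {
  stopifnot(length(counts) == length(printed_pct), denominator > 0)
  recomputed <- round(100 * counts / denominator, 1)
  data.frame(count = counts, printed_pct = printed_pct,
             recomputed_pct = recomputed,
             consistent = abs(recomputed - printed_pct) < 0.05)
}

#' Age-stratified association of PRS risk group with LOY
#'
#' Fits `is_loy ~ risk_group + current_smoker + current_alcohol` separately
#' within each age stratum (age is excluded within strata by design). Bins
#' are left-closed, right-open, the last unbounded: with the default edges,
#' 70-74, 75-79 and 80+. A stratum missing an outcome class or containing
#' fewer than two PRS groups is reported as unestimable rather than dropped.
#'
#' @param data Data.frame with `age`, `is_loy`, `risk_group`, `smoking`,
#'   `alcohol`.
#' @param bins Increasing left bin edges (default `c(70, 75, 80)`).
#' @return Named list per stratum: either an `assoc_result` or the string
#'   `"unestimable"` with a reason attribute.
#' @export
age_stratified_association <- function(data, bins = c(70, 75, 80)) {
  labels <- c(paste(bins[-length(bins)], bins[-1] - 1, sep = "-"),
              paste0(bins[length(bins)], "+"))
  data$stratum <- cut(data$age, c(bins, Inf), right = FALSE, labels = labels)
  out <- lapply(labels, function(lb) {
    sub <- data[!is.na(data$stratum) & data$stratum == lb &
                  !is.na(data$is_loy), ]
    sub$risk_group <- droplevels(factor(sub$risk_group,
                                        levels = c("low", "middle", "high")))
    if (length(unique(sub$is_loy)) < 2 || nlevels(sub$risk_group) < 2) {
      return(structure("unestimable",
                       reason = "needs both outcomes and >= 2 PRS groups"))
    }
    sub$current_smoker <- encode_current(sub$smoking)
    sub$current_alcohol <- encode_current(sub$alcohol)
    # a covariate constant within the stratum carries no information and
    # would only make the design rank-deficient: omit it there
    covs <- c("current_smoker", "current_alcohol")
    covs <- covs[vapply(covs, function(v) length(unique(sub[[v]])) > 1,
                        logical(1))]
    fml <- stats::reformulate(c("risk_group", covs), response = "is_loy")
    tryCatch(fit_logistic(fml, sub), error = function(e) {
      structure("unestimable", reason = conditionMessage(e))
    })
  })
  names(out) <- labels
  out
}
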