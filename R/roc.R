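# AUC and DeLong machinery for comparing correlated ROC curves.
#
# The AUC is computed through the rank (Mann-Whitney) identity; variances
# and covariances come from DeLong's structural components, evaluated with
# midranks so ties are handled exactly.

# Structural components of one score vector: V10 (per case) and V01 (per
# control), whose means equal the AUC.
delong_components <- function(score, labels) {
  stopifnot(length(score) == length(labels), all(labels %in% c(0, 1)))
  ok <- !is.na(score) & !is.na(labels)
  score <- score[ok]; labels <- labels[ok]
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m == 0 || n == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  x <- score[labels == 1]
  y <- score[labels == 0]
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC via the rank/Mann-Whitney identity (ties count one half), with a
#' normal-approximation 95% confidence interval from the DeLong
#' structural-component variance.
#'
#' @param predicted Numeric risk scores.
#' @param labels 0/1 outcome labels, aligned with `predicted`.
#' @param conf_level Confidence level.
#' @return A list (`auc`, `se`, `ci_low`, `ci_high`, `n_pos`, `n_neg`).
#' @export
roc_auc <- function(predicted, labels, conf_level = 0.95) {
  cmp <- delong_components(predicted, labels)
  v <- var(cmp$v10) / cmp$m + var(cmp$v01) / cmp$n
  zq <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  list(auc = cmp$auc, se = se,
       ci_low = max(0, cmp$auc - zq * se),
       ci_high = min(1, cmp$auc + zq * se),
       n_pos = cmp$m, n_neg = cmp$n)
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same samples,
#' accounting for their correlation through the covariance of the DeLong
#' structural components. Two identical score vectors give z = 0, p = 1.
#'
#' @param pred_model1,pred_model2 Numeric risk scores, paired on the same
#'   samples.
#' @param labels 0/1 outcome labels.
#' @return A list (`auc1`, `auc2`, `delta`, `z`, `p_value`).
#' @export
delong_test <- function(pred_model1, pred_model2, labels) {
  stopifnot(length(pred_model1) == length(pred_model2))
  c1 <- delong_components(pred_model1, labels)
  c2 <- delong_components(pred_model2, labels)
  s10 <- cov(cbind(c1$v10, c2$v10))
  s01 <- cov(cbind(c1$v01, c2$v01))
  v_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / c1$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / c1$n
  delta <- c1$auc - c2$auc
  if (v_delta <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(v_delta)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc1 = c1$auc, auc2 = c2$auc, delta = delta, z = z, p_value = p)
}

#' Compare a base LOY prediction model against base + PRS
#'
#' Fits two in-sample logistic models on the same data — the base model
#' (age, current smoking, current alcohol) and the base model plus the
#' standardised PRS — and compares their ROC curves with DeLong's test.
#'
#' @param data Data.frame with `is_loy`, `age`, `smoking`, `alcohol`,
#'   `z_score`.
#' @return A list (`auc_base`, `auc_full` — each a [roc_auc()] record —
#'   `delong` — a [delong_test()] record).
#' @export
compare_prediction_models <- function(data) {
  d <- data[!is.na(data$is_loy) & !is.na(data$z_score), ]
  d$current_smoker <- encode_current(d$smoking)
  d$current_alcohol <- encode_current(d$alcohol)
  base <- glm(is_loy ~ age + current_smoker + current_alcohol,
              data = d, family = binomial())
  full <- glm(is_loy ~ age + current_smoker + current_alcohol + z_score,
              data = d, family = binomial())
  p_base <- predict(base, type = "response")
  p_full <- predict(full, type = "response")
  list(auc_base = roc_auc(p_base, d$is_loy),
       auc_full = roc_auc(p_full, d$is_loy),
       delong = delong_test(p_full, p_base, d$is_loy))
}
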