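expand_2x2 <- function(a, b, c, d) {
  # a: exposed cases, b: exposed controls, c: unexposed cases, d: unexposed
  data.frame(y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
             x = rep(c(1, 1, 0, 0), c(a, b, c, d)))
}

test_that("logistic fit reproduces the analytic 2x2 odds ratio and SE", {
  set.seed(31)
  for (rep in 1:5) {
    cnt <- sample(20:200, 4)
    d <- expand_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    fit <- fit_logistic(y ~ x, d)
    or_hat <- fit$odds_ratio[fit$term == "x"]
    se_hat <- fit$se[fit$term == "x"]
    expect_equal(or_hat, (cnt[1] * cnt[4]) / (cnt[2] * cnt[3]),
                 tolerance = 1e-6)
    expect_equal(se_hat, sqrt(sum(1 / cnt)), tolerance = 1e-6)
    expect_true(fit$ci_low[2] <= or_hat && or_hat <= fit$ci_high[2])
  }
})

test_that("degenerate logistic designs raise informative errors", {
  d <- expand_2x2(30, 40, 20, 50)
  d$x2 <- d$x  # collinear copy
  expect_error(fit_logistic(y ~ x + x2, d), "rank-deficient")

  sep <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  expect_error(fit_logistic(y ~ x, sep), "separation")

  expect_error(fit_logistic(y ~ x, data.frame(y = c(1, 2, 3), x = 1:3)),
               "binary")
})

test_that("linear fit is exact on noiseless data", {
  d <- data.frame(x1 = c(1, 2, 3, 4, 5), x2 = c(0, 1, 0, 1, 0))
  d$y <- 2 + 3 * d$x1 - 1.5 * d$x2
  # lm flags the perfect fit; the point here is exactness of the estimates
  fit <- suppressWarnings(fit_linear(y ~ x1 + x2, d))
  expect_equal(fit$estimate, c(2, 3, -1.5), tolerance = 1e-10)

  m <- fit_linear(y ~ 1, data.frame(y = c(1, 4, 7)))
  expect_equal(m$estimate, 4)
})

test_that("orthogonal predictors give univariate slopes", {
  set.seed(32)
  x1 <- rep(c(-1, 1), 20)
  x2 <- rep(c(-1, -1, 1, 1), 10)  # orthogonal to x1 and centred
  y <- rnorm(40)
  joint <- fit_linear(y ~ x1 + x2, data.frame(y, x1, x2))
  uni1 <- fit_linear(y ~ x1, data.frame(y, x1))
  uni2 <- fit_linear(y ~ x2, data.frame(y, x2))
  expect_equal(joint$estimate[2], uni1$estimate[2], tolerance = 1e-10)
  expect_equal(joint$estimate[3], uni2$estimate[2], tolerance = 1e-10)
})

test_that("ANCOVA without covariates reduces to the pooled t-test", {
  set.seed(33)
  prs <- rnorm(200)
  loy <- rbinom(200, 1, 0.3)
  anc <- ancova_prs(prs, loy)
  tt <- t_test(prs[loy == 1], prs[loy == 0], var_equal = TRUE)
  expect_equal(anc$p_value, tt$p_value, tolerance = 1e-6)
  expect_equal(anc$adjusted_means[["yes"]] - anc$adjusted_means[["no"]],
               mean(prs[loy == 1]) - mean(prs[loy == 0]), tolerance = 1e-10)
})

test_that("ANCOVA detects a 0.5 SD PRS shift with covariate adjustment", {
  set.seed(34)
  n <- 5000
  cov <- data.frame(age = runif(n, 70, 90),
                    smoking = sample(c("never", "former", "current"), n, TRUE),
                    alcohol = sample(c("never", "former", "current"), n, TRUE))
  loy <- rbinom(n, 1, 0.27)
  prs <- rnorm(n) + 0.5 * loy
  anc <- ancova_prs(prs, loy, cov)
  expect_lt(anc$p_value, 0.001)
  expect_gt(anc$adjusted_means[["yes"]], anc$adjusted_means[["no"]])
})

test_that("chi-square test matches the direct formula and edge rules", {
  flat <- matrix(c(10, 10, 20, 20), 2)
  out <- chi_square_test(flat)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  set.seed(35)
  tab <- matrix(sample(5:80, 4), 2)
  got <- chi_square_test(tab)
  exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_cnt)^2 / exp_cnt)
  expect_equal(got$statistic, stat, tolerance = 1e-10)
  expect_equal(got$df, 1)
  expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero row or column")
})

test_that("smoking-by-LOY counts of cohort scale are clearly associated", {
  tab <- matrix(c(1680, 573, 1952, 747, 107, 72), nrow = 3, byrow = TRUE,
                dimnames = list(c("never", "former", "current"),
                                c("no", "yes")))
  expect_lt(chi_square_test(tab)$p_value, 0.001)
})

test_that("t-test and rank-sum handle identical, shifted and tied input", {
  x <- c(1, 2, 3, 4)
  same <- t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(t_test(rep(1, 5), rep(1, 5))$p_value, 1)

  set.seed(36)
  a <- rnorm(200); b <- rnorm(200) + 2
  expect_lt(t_test(a, b)$p_value, 0.001)
  expect_lt(wilcoxon_rank_sum(a, b)$p_value, 0.001)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 6))$p_value, 1)
})

test_that("rank-sum U equals the exhaustive permutation oracle", {
  set.seed(37)
  for (rep in 1:5) {
    a <- sample(1:20, sample(4:8, 1), replace = TRUE)
    b <- sample(1:20, sample(4:8, 1), replace = TRUE)
    got <- wilcoxon_rank_sum(a, b)
    want <- oracle_wilcoxon(a, b)
    expect_equal(got$statistic, want$u)
    # normal approximation with tie correction tracks the exact p closely
    expect_equal(got$p_value, want$p, tolerance = 0.06)
  }
})

test_that("AUC equals the brute-force pairwise concordance count", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)

  set.seed(38)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    score <- sample(1:15, n, replace = TRUE)  # plenty of ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    got <- roc_auc(score, labels)
    expect_equal(got$auc, oracle_auc(score, labels), tolerance = 1e-12)
    expect_true(got$ci_low <= got$auc && got$auc <= got$ci_high)
  }
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "both outcome classes")
})

test_that("AUC and DeLong test agree with the pROC reference", {
  set.seed(39)
  n <- 300
  labels <- rbinom(n, 1, 0.35)
  s1 <- labels + rnorm(n)
  s2 <- labels + rnorm(n, sd = 2)
  got_auc <- roc_auc(s1, labels)
  ref <- pROC::roc(labels, s1, quiet = TRUE, direction = "<")
  expect_equal(got_auc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(got_auc$ci_low, got_auc$ci_high), ref_ci[c(1, 3)],
               tolerance = 1e-6)

  got <- delong_test(s1, s2, labels)
  ref2 <- pROC::roc(labels, s2, quiet = TRUE, direction = "<")
  ref_test <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(got$p_value, ref_test$p.value, tolerance = 1e-6)
})

test_that("identical prediction vectors give DeLong p = 1", {
  set.seed(40)
  s <- rnorm(100)
  y <- rbinom(100, 1, 0.5)
  out <- delong_test(s, s, y)
  expect_equal(out$z, 0)
  expect_equal(out$p_value, 1)
})

test_that("age strata use left-closed bins and report unestimable cells", {
  set.seed(41)
  n <- 900
  d <- data.frame(
    age = runif(n, 70, 92),
    risk_group = factor(sample(c("low", "middle", "high"), n, TRUE),
                        levels = c("low", "middle", "high")),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    alcohol = sample(c("never", "former", "current"), n, TRUE)
  )
  d$is_loy <- rbinom(n, 1, 0.3)  # homogeneous risk
  out <- age_stratified_association(d)
  expect_equal(names(out), c("70-74", "75-79", "80+"))
  ors <- unlist(lapply(out, function(f) {
    f$odds_ratio[grepl("risk_group", f$term)]
  }))
  expect_true(all(ors > 0.3 & ors < 3.5))  # within ~3 SE of 1 under the null

  # boundary ages: 75.0 is in 75-79, 80.0 in 80+
  d2 <- d
  d2$age <- rep(c(72, 75, 80), length.out = n)
  out2 <- age_stratified_association(d2)
  expect_equal(attr(out2[["75-79"]], "n"), sum(d2$age == 75))
  expect_equal(attr(out2[["80+"]], "n"), sum(d2$age == 80))

  # a stratum with one outcome class is unestimable, not dropped
  d3 <- d
  d3$is_loy[d3$age >= 80] <- 1L
  out3 <- age_stratified_association(d3)
  expect_equal(unclass(out3[["80+"]])[1], "unestimable")
})

test_that("baseline table recomputes counts, percentages and tests", {
  ds <- default_dataset()
  rep <- analyze_loy_dataset(ds, with_wgs = FALSE)
  bt <- rep$baseline
  expect_equal(bt$n, 5131)
  smk <- bt$categorical$smoking
  expect_equal(sum(smk$n_all), 5131)
  expect_equal(smk$pct_all, round(100 * smk$n_all / 5131, 1))
  # smoking and age differ by LOY status under the generative model
  # (current smokers are only 3.5% of the cohort, so power is modest)
  expect_lt(attr(smk, "p_value"), 0.05)
  expect_lt(bt$age$p_value, 0.001)
  expect_gt(bt$age$mean_yes, bt$age$mean_no)
  # treatment is independent of LOY by construction
  expect_gt(attr(bt$categorical$treatment, "p_value"), 0.01)
})

test_that("printed-percentage verification flags inconsistent cells", {
  v <- verify_table_percentages(c(2253, 2699, 179), c(43.9, 52.6, 3.5), 5131)
  expect_true(all(v$consistent))
  v2 <- verify_table_percentages(c(2633), c(52.1), 5131)
  expect_false(any(v2$consistent))
  expect_equal(v2$recomputed_pct, 51.3)
})
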