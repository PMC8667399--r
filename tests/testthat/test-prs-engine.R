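write_score <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("score files are parsed and validated", {
  cfg156 <- sim_config(n_samples = 5, n_variants = 156, seed = 2)
  g <- generate_genotypes(cfg156)
  path <- write_score(g$score)
  sv <- read_score_file(path)
  expect_equal(nrow(sv), 156)

  empty <- write_score(g$score[0, ])
  expect_equal(nrow(read_score_file(empty)), 0)

  bad <- g$score[1:3, ]
  bad$other_allele[2] <- bad$effect_allele[2]
  expect_error(read_score_file(write_score(bad)), "identical at line 3")

  dup <- g$score[c(1, 1, 2), ]
  expect_error(read_score_file(write_score(dup)), "duplicate variant_id")

  mal <- g$score[1:3, ]
  mal$weight[3] <- NA
  expect_error(read_score_file(write_score(mal)), "line 4")
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)   # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), 1)  # modal configuration

  set.seed(11)
  for (rep in 1:40) {
    n <- sample(1:200, 1)
    a <- sample(0:n, 1)
    h <- sample(0:(n - a), 1)
    b <- n - a - h
    expect_equal(hwe_exact_test(a, h, b), oracle_hwe(a, h, b),
                 tolerance = 1e-10,
                 info = sprintf("counts (%d,%d,%d)", a, h, b))
  }
})

test_that("HWE test flags distorted genotypes but not HWE draws", {
  set.seed(12)
  p <- 0.4; n <- 2000
  g_ok <- rbinom(n, 2, p)
  p_ok <- hwe_exact_test(sum(g_ok == 0), sum(g_ok == 1), sum(g_ok == 2))
  expect_gt(p_ok, 0.01)
  # strong excess homozygosity
  g_bad <- sample(0:2, n, replace = TRUE,
                  prob = c((1 - p)^2 + 0.5 * p * (1 - p),
                           2 * p * (1 - p) * 0.5, p^2 + 0.5 * p * (1 - p)))
  p_bad <- hwe_exact_test(sum(g_bad == 0), sum(g_bad == 1), sum(g_bad == 2))
  expect_lt(p_bad, 1e-10)
})

test_that("variant QC applies the documented threshold conventions", {
  meta <- data.frame(variant_id = sprintf("v%d", 1:5),
                     call_rate = c(0.90, 0.901, 1, 1, 1),
                     hwe_p = c(0.5, 0.5, 1e-7, 0.5, 0.5),
                     imputation_r2 = c(1, 1, 1, 0.29, 0.30))
  qc <- variant_qc(meta)
  # call rate must be strictly above 0.90; r2 exactly 0.30 is retained
  expect_equal(qc$qc_pass, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  rep <- attr(qc, "qc_report")
  expect_equal(rep$n_failed[rep$filter == "any"], 3)

  perfect <- data.frame(variant_id = "v", call_rate = 1, hwe_p = 0.5,
                        imputation_r2 = 1)
  expect_true(all(variant_qc(perfect)$qc_pass))
})

test_that("allele alignment flips, drops and cross-checks correctly", {
  sv <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   chrom = c(1, 1, 2, 2), pos = c(100, 200, 300, 400),
                   effect_allele = c("A", "A", "C", "G"),
                   other_allele = c("G", "C", "T", "A"),
                   weight = c(0.1, -0.2, 0.3, 0.4))
  dm <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   chrom = c(1, 1, 2, 9), pos = c(100, 200, 300, 400),
                   counted_allele = c("A", "C", "G", "G"),
                   other_allele = c("G", "A", "T", "A"))
  expect_warning(al <- align_alleles(sv, dm), "chrom/pos")
  # v1 as-is, v2 flipped, v3 allele-incompatible, v4 position mismatch
  expect_equal(al$variant_id, c("v1", "v2"))
  expect_equal(al$flip, c(FALSE, TRUE))
  expect_equal(attr(al, "dropped")[["allele_incompatible"]], 1)
  expect_equal(attr(al, "dropped")[["pos_mismatch"]], 1)
})

test_that("PRS equals the nested-loop oracle and is flip-invariant", {
  set.seed(13)
  n <- 10; m <- 5
  geno <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                 dimnames = list(sprintf("S%02d", 1:n), sprintf("v%d", 1:m)))
  w <- rnorm(m)
  sv <- data.frame(variant_id = sprintf("v%d", 1:m),
                   effect_allele = "A", other_allele = "G", weight = w)
  flip <- c(FALSE, TRUE, TRUE, FALSE, TRUE)
  dm <- data.frame(variant_id = sprintf("v%d", 1:m),
                   counted_allele = ifelse(flip, "G", "A"),
                   other_allele = ifelse(flip, "A", "G"))
  dos <- geno
  dos[, flip] <- 2 - dos[, flip]  # dosage file counts the other allele
  al <- align_alleles(sv, dm)
  prs <- compute_prs(dos, al)
  expect_equal(unname(prs), oracle_prs(geno, w), tolerance = 1e-12)
})

test_that("PRS handles trivial and missing-dosage cases", {
  dos <- matrix(c(2, 1, 0, NA), 2, 2,
                dimnames = list(c("a", "b"), c("v1", "v2")))
  al0 <- data.frame(variant_id = c("v1", "v2"), weight = c(0, 0),
                    flip = FALSE)
  expect_equal(unname(compute_prs(dos, al0)), c(0, 0))

  al1 <- data.frame(variant_id = "v1", weight = log(2), flip = FALSE)
  expect_equal(unname(compute_prs(dos, al1)), c(2 * log(2), log(2)))

  # missing dosage mean-imputed as 2 * observed effect-allele frequency
  dos3 <- matrix(c(2, 0, 1, 1, NA, 1), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("v1", "v2")))
  al3 <- data.frame(variant_id = c("v1", "v2"), weight = c(1, 1),
                    flip = FALSE)
  imputed_v2 <- 2 * mean(c(1, 1)) / 2
  expect_equal(unname(compute_prs(dos3, al3)),
               c(2 + 1, 0 + imputed_v2, 1 + 1))

  # a sample missing every dosage scores NA
  dos_na <- matrix(c(NA, 1), 2, 1, dimnames = list(c("a", "b"), "v1"))
  expect_true(is.na(compute_prs(dos_na, al1)["a"]))
})

test_that("PRS is linear in the weights", {
  set.seed(14)
  dos <- matrix(sample(0:2, 60, replace = TRUE), 12, 5,
                dimnames = list(NULL, sprintf("v%d", 1:5)))
  rownames(dos) <- sprintf("S%02d", 1:12)
  mk <- function(w) data.frame(variant_id = sprintf("v%d", 1:5), weight = w,
                               flip = FALSE)
  w1 <- rnorm(5); w2 <- rnorm(5)
  expect_equal(compute_prs(dos, mk(w1 + w2)),
               compute_prs(dos, mk(w1)) + compute_prs(dos, mk(w2)),
               tolerance = 1e-12)
})

test_that("standardisation and quintile grouping partition the cohort", {
  res <- standardize_and_group(setNames(1:10, paste0("s", 1:10)))
  expect_equal(as.character(res$risk_group),
               c("low", "low", rep("middle", 6), "high", "high"))
  expect_lt(abs(mean(res$z_score)), 1e-12)
  expect_equal(sd(res$z_score), 1, tolerance = 1e-12)

  # n = 5131: 1026 / 3079 / 1026 by rank arithmetic
  set.seed(15)
  big <- standardize_and_group(setNames(rnorm(5131), sprintf("S%04d", 1:5131)))
  expect_equal(unname(table(big$risk_group)),
               c(1026L, 3079L, 1026L), ignore_attr = TRUE)
  expect_equal(sum(table(big$risk_group)), 5131)

  # ties broken by stable order still partition
  tied <- standardize_and_group(setNames(rep(c(1, 2), 5), paste0("t", 1:10)))
  expect_equal(sum(table(tied$risk_group)), 10)

  expect_error(standardize_and_group(rep(1, 10)), "zero variance")
  expect_error(standardize_and_group(c(1, 2, 3)), "at least 5")
})
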