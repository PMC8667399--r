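# Shared fixtures, built once per test run.

# A small but fully featured cohort: every stage runs in well under a second.
small_config <- function(seed = 42, ...) {
  defaults <- list(n_samples = 400, n_variants = 40, n_msy_probes = 60,
                   n_autosomal_probes = 40, n_wgs_samples = 60,
                   n_wgs_msy_windows = 40, n_wgs_auto_windows = 80,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixtures <- new.env()

# Full-size dataset at the generator defaults, reused across files.
default_dataset <- function() {
  if (is.null(.fixtures$default_ds)) {
    .fixtures$default_ds <- simulate_dataset(sim_config(seed = 20260921))
  }
  .fixtures$default_ds
}

small_dataset <- function() {
  if (is.null(.fixtures$small_ds)) {
    .fixtures$small_ds <- simulate_dataset(small_config())
  }
  .fixtures$small_ds
}

# Independent sort-based median: oracle for compute_mlrry.
oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Independent HWE enumeration oracle: probabilities proportional to
# exp(lchoose(n, a) + lchoose(n - a, h) + h * log(2)), a different
# decomposition of the conditional law than the implementation uses.
oracle_hwe <- function(a, h, b) {
  n <- a + h + b
  n_minor <- min(2 * a + h, 2 * b + h)
  if (n_minor == 0) return(1)
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  as <- (2 * a + h - hs) / 2
  lw <- lchoose(n, as) + lchoose(n - as, hs) + hs * log(2)
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  p_obs <- p[hs == h]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# All-pairs concordance count: oracle for roc_auc.
oracle_auc <- function(score, labels) {
  pos <- score[labels == 1]
  neg <- score[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Nested-loop weighted sum: oracle for compute_prs (no missing values).
oracle_prs <- function(dosages, weights) {
  out <- numeric(nrow(dosages))
  for (i in seq_len(nrow(dosages))) {
    s <- 0
    for (j in seq_len(ncol(dosages))) s <- s + weights[j] * dosages[i, j]
    out[i] <- s
  }
  out
}

# Exact permutation null of the Mann-Whitney U statistic.
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * (n - n1) / 2
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}
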