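#' Per-sample median Log R Ratio over MSY probes (mLRRY)
#'
#' The mLRRY is the median LRR across the probes of the male-specific region
#' of chromosome Y, computed per sample over non-missing values. It sits
#' near 0 in unaffected men and drifts negative as the fraction of cells
#' without a Y chromosome grows. Samples with no usable MSY probe are
#' returned with `mlrry = NA` and flagged unscorable (a message reports the
#' count); downstream callers treat them as missing.
#'
#' @param lrr Probes x samples numeric matrix of LRR values, rownames =
#'   probe ids, colnames = sample ids.
#' @param probe_annotation Data.frame with at least `probe_id` and a logical
#'   `is_msy` column marking MSY probes.
#' @return A data.frame (`sample_id`, `mlrry`, `n_probes_used`).
#' @export
compute_mlrry <- function(lrr, probe_annotation) {
  stopifnot(is.matrix(lrr), !is.null(rownames(lrr)), !is.null(colnames(lrr)))
  msy_ids <- probe_annotation$probe_id[probe_annotation$is_msy]
  msy_ids <- intersect(msy_ids, rownames(lrr))
  if (length(msy_ids) == 0) {
    stop("no MSY-flagged probes present in the LRR matrix", call. = FALSE)
  }
  sub <- lrr[msy_ids, , drop = FALSE]
  n_used <- colSums(!is.na(sub))
  mlrry <- apply(sub, 2, median, na.rm = TRUE)
  mlrry[n_used == 0] <- NA_real_
  if (any(n_used == 0)) {
    message(sum(n_used == 0),
            " sample(s) had no usable MSY probe and are unscorable")
  }
  data.frame(sample_id = colnames(lrr), mlrry = unname(mlrry),
             n_probes_used = unname(as.integer(n_used)),
             stringsAsFactors = FALSE)
}

#' Calling threshold from a reflected experimental-error null
#'
#' LOY only ever pulls mLRRY downwards, so the spread of values at and above
#' the central mode is attributable to technical noise alone. The mode is
#' located by kernel density estimation (Gaussian kernel, Silverman plug-in
#' bandwidth) restricted to a robust interval around the median; a symmetric
#' null is then built by reflecting the observations at or above the mode to
#' the other side, and the threshold is set the same distance below the mode
#' as the null's upper `1 - percentile` quantile sits above it. For Gaussian
#' noise with SD `s` and the default percentile 0.005 this converges to
#' `mode - 2.576 * s`.
#'
#' @param mlrry_values Numeric vector of per-sample mLRRY values (NAs
#'   dropped).
#' @param percentile Lower tail probability of the symmetric null used as
#'   the calling point; must be in (0, 0.5).
#' @return A list of class `loy_threshold`: `mode`, `threshold`,
#'   `percentile`, `method` (`"reflected_null"` or `"fixed"`), `n`.
#' @export
estimate_threshold <- function(mlrry_values, percentile = 0.005) {
  stopifnot(percentile > 0, percentile < 0.5)
  x <- mlrry_values[!is.na(mlrry_values)]
  if (length(x) == 0) stop("no mLRRY values supplied", call. = FALSE)
  if (length(x) < 100) {
    warning("fewer than 100 samples: threshold estimate will be unstable")
  }
  if (diff(range(x)) == 0) {
    warning("degenerate null: all mLRRY values identical")
    return(structure(list(mode = x[1], threshold = x[1],
                          percentile = percentile, method = "reflected_null",
                          n = length(x)),
                     class = "loy_threshold"))
  }
  ctr <- median(x)
  hw <- max(3 * mad(x), 1e-8)
  # Oversmoothing (3x the plug-in bandwidth) cuts the variance of the peak
  # location; it does not bias the centre of a symmetric null, and the
  # LOY contamination sits far in the left tail where the kernel weight is
  # negligible. The discrete argmax is refined by parabolic interpolation.
  dens <- density(x, from = ctr - hw, to = ctr + hw, n = 4096, adjust = 3)
  i <- which.max(dens$y)
  mode <- dens$x[i]
  if (i > 1 && i < length(dens$x)) {
    y3 <- dens$y[(i - 1):(i + 1)]
    curv <- y3[1] - 2 * y3[2] + y3[3]
    if (curv < 0) {
      mode <- mode - 0.5 * (y3[3] - y3[1]) / curv * (dens$x[2] - dens$x[1])
    }
  }
  dev <- x[x >= mode] - mode
  sym <- c(mode + dev, mode - dev)
  upper <- quantile(sym, 1 - percentile, names = FALSE, type = 8)
  structure(list(mode = mode, threshold = mode - (upper - mode),
                 percentile = percentile, method = "reflected_null",
                 n = length(x)),
            class = "loy_threshold")
}

#' A fixed calling threshold
#'
#' Wraps a user-chosen mLRRY cut-off (for example the published operating
#' point of -0.06) in the same object returned by [estimate_threshold()].
#'
#' @param threshold mLRRY cut-off in LRR units.
#' @return A `loy_threshold` object with `method = "fixed"`.
#' @export
fixed_threshold <- function(threshold = -0.06) {
  stopifnot(is.finite(threshold))
  structure(list(mode = 0, threshold = threshold, percentile = NA_real_,
                 method = "fixed", n = NA_integer_),
            class = "loy_threshold")
}

#' @export
print.loy_threshold <- function(x, ...) {
  cat(sprintf("LOY calling threshold: %.4f (method %s, mode %.4f, n %s)\n",
              x$threshold, x$method, x$mode,
              ifelse(is.na(x$n), "-", x$n)))
  invisible(x)
}

#' Convert mLRRY to the percentage of cells with LOY
#'
#' Under a linear-intensity mixture of diploid and Y-null cells, the
#' expected LRR shift of the MSY region is `c * log2(1 - f)` where `f` is
#' the fraction of affected cells and `c` the array response factor.
#' Inverting gives `f = 1 - 2^(mLRRY / c)`. With the default `c = 0.46`,
#' an mLRRY of -0.06 corresponds to 8.6% of cells. Positive mLRRY maps to
#' 0% (a proportion cannot be negative).
#'
#' @param mlrry Numeric vector of mLRRY values.
#' @param response_factor Array response factor `c` in (0, 1].
#' @return Percentage of cells with LOY, in \[0, 100\].
#' @export
#' @examples
#' mlrry_to_fraction(-0.06)  # 8.6
mlrry_to_fraction <- function(mlrry, response_factor = 0.46) {
  stopifnot(response_factor > 0, response_factor <= 1)
  f <- 1 - 2^(mlrry / response_factor)
  100 * pmin(pmax(f, 0), 1)
}

#' Binary and continuous LOY calls
#'
#' A sample is called LOY-positive when its mLRRY is strictly below the
#' threshold. Both the continuous variables (mLRRY, percent of cells) and
#' the binary call are retained; unscorable samples (missing mLRRY)
#' propagate as NA.
#'
#' @param mlrry_results Output of [compute_mlrry()].
#' @param threshold A `loy_threshold` object or a bare numeric cut-off.
#' @param response_factor Passed to [mlrry_to_fraction()].
#' @return A data.frame (`sample_id`, `mlrry`, `n_probes_used`,
#'   `fraction_pct`, `is_loy`, `threshold_used`).
#' @export
call_loy <- function(mlrry_results, threshold, response_factor = 0.46) {
  thr <- if (inherits(threshold, "loy_threshold")) threshold$threshold
         else threshold
  stopifnot(is.finite(thr))
  out <- mlrry_results[, c("sample_id", "mlrry", "n_probes_used")]
  out$fraction_pct <- mlrry_to_fraction(out$mlrry, response_factor)
  out$is_loy <- as.integer(out$mlrry < thr)  # strict inequality
  out$threshold_used <- thr
  out
}

#' LOY prevalence by age bin
#'
#' Tabulates counts and percentage of LOY-positive samples per age bin.
#' Bins are left-closed, right-open; the last bin is unbounded above. An
#' empty bin reports `NA` (not 0) percent. Optionally compares the mLRRY
#' distributions of two named bins with a Wilcoxon rank-sum test.
#'
#' @param calls Output of [call_loy()].
#' @param covariates Data.frame with `sample_id` and `age`.
#' @param bin_edges Increasing left edges of the bins, e.g. `c(70, 75, 80, 85)`.
#' @param compare Optional character vector of two bin labels whose mLRRY
#'   distributions are compared.
#' @return A data.frame (`age_bin`, `n`, `n_loy`, `pct_loy`); when
#'   `compare` is given, a `wilcoxon` attribute holds the test result.
#' @export
prevalence_by_age <- function(calls, covariates, bin_edges = c(70, 75, 80, 85),
                              compare = NULL) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  d <- merge(calls, covariates[, c("sample_id", "age")], by = "sample_id")
  labels <- c(paste(bin_edges[-length(bin_edges)],
                    bin_edges[-1] - 1, sep = "-"),
              paste0(bin_edges[length(bin_edges)], "+"))
  d$age_bin <- cut(d$age, c(bin_edges, Inf), right = FALSE, labels = labels)
  tab <- lapply(labels, function(lb) {
    sub <- d[d$age_bin == lb & !is.na(d$is_loy), ]
    data.frame(age_bin = lb, n = nrow(sub), n_loy = sum(sub$is_loy),
               pct_loy = if (nrow(sub) > 0) 100 * mean(sub$is_loy) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tab)
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2, all(compare %in% labels))
    a <- d$mlrry[d$age_bin == compare[1] & !is.na(d$mlrry)]
    b <- d$mlrry[d$age_bin == compare[2] & !is.na(d$mlrry)]
    attr(out, "wilcoxon") <- wilcoxon_rank_sum(a, b)
  }
  out
}
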