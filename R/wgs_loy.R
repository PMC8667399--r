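#' LOY estimate from WGS read-depth windows
#'
#' In an unaffected male the MSY is haploid, so its expected per-window read
#' count is half the autosomal one. The Y dosage is summarised as
#' `y_log2_ratio = log2(mean MSY count / (0.5 * mean autosomal count))`,
#' which is 0 in an unaffected sample and `log2(1 - f)` when a fraction `f`
#' of cells has lost the Y; the implied percentage of affected cells is
#' `100 * (1 - 2^ratio)` clamped to \[0, 100\].
#'
#' @param depth_windows Data.frame with columns `sample_id`, `region`
#'   (`"MSY"` or `"autosomal"`) and `read_count`, as produced by
#'   [generate_wgs_depth()] or read from a BED-like file.
#' @param summary_fun Window summary, `"mean"` (default) or `"median"`; the
#'   median is the robust choice for real data with outlier windows.
#' @return A data.frame (`sample_id`, `y_log2_ratio`, `fraction_pct`).
#'   Samples with zero total autosomal coverage are unscorable and returned
#'   with NAs.
#' @export
depth_log_ratio <- function(depth_windows, summary_fun = c("mean", "median")) {
  summary_fun <- match.arg(summary_fun)
  fn <- if (summary_fun == "mean") mean else median
  stopifnot(all(c("sample_id", "region", "read_count") %in%
                  names(depth_windows)),
            all(depth_windows$read_count >= 0))
  ids <- unique(depth_windows$sample_id)
  rows <- lapply(ids, function(id) {
    sub <- depth_windows[depth_windows$sample_id == id, ]
    msy <- sub$read_count[sub$region == "MSY"]
    aut <- sub$read_count[sub$region == "autosomal"]
    if (length(msy) < 1 || length(aut) < 1) {
      stop("sample ", id, " lacks windows in one region class", call. = FALSE)
    }
    if (sum(aut) == 0) {
      return(data.frame(sample_id = id, y_log2_ratio = NA_real_,
                        fraction_pct = NA_real_, stringsAsFactors = FALSE))
    }
    ratio <- log2(fn(msy) / (0.5 * fn(aut)))
    data.frame(sample_id = id, y_log2_ratio = ratio,
               fraction_pct = min(max(100 * (1 - 2^ratio), 0), 100),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance between array-derived and WGS-derived LOY estimates
#'
#' Pairs the two estimates by `sample_id` and reports the Pearson
#' correlation over complete pairs. Samples missing on either side are
#' excluded and counted.
#'
#' @param array_values Data.frame with `sample_id` and a value column.
#' @param wgs_values Data.frame with `sample_id` and a value column.
#' @param array_col,wgs_col Names of the value columns.
#' @return A list (`r`, `n`, `excluded`).
#' @export
loy_concordance <- function(array_values, wgs_values,
                            array_col = "mlrry", wgs_col = "y_log2_ratio") {
  a <- array_values[, c("sample_id", array_col)]
  b <- wgs_values[, c("sample_id", wgs_col)]
  names(a)[2] <- "x"; names(b)[2] <- "y"
  m <- merge(a, b, by = "sample_id")
  ok <- complete.cases(m$x, m$y)
  n_excluded <- (nrow(array_values) + nrow(wgs_values) - 2 * sum(ok))
  m <- m[ok, ]
  if (nrow(m) < 3) {
    stop("fewer than 3 complete pairs: concordance undefined", call. = FALSE)
  }
  if (sd(m$x) == 0 || sd(m$y) == 0) {
    stop("zero variance on one side: Pearson correlation undefined",
         call. = FALSE)
  }
  list(r = cor(m$x, m$y), n = nrow(m), excluded = n_excluded)
}
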