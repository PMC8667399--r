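write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a complete synthetic dataset to disk
#'
#' Simulates a dataset under `config` and writes every table as plain text:
#' covariates, dosage matrix (samples x variants), dosage variant metadata,
#' score file, LRR matrix (probes x samples), BED-style probe annotation,
#' WGS depth windows, the ground-truth state, and a `manifest.json`
#' carrying the seed and a hash of the full configuration. Re-running with
#' the same seed reproduces every file byte for byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
cmd_simulate <- function(config = sim_config(), out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir,
         " exists and is non-empty; use force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config)

  write_tsv(ds$covariates, file.path(out_dir, "covariates.tsv"))
  dos <- data.frame(sample_id = rownames(ds$genotypes$dosages),
                    ds$genotypes$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(dos, file.path(out_dir, "dosages.tsv"))
  write_tsv(ds$genotypes$meta, file.path(out_dir, "dosage_meta.tsv"))
  write_tsv(ds$genotypes$score, file.path(out_dir, "score.tsv"))
  lrr <- data.frame(probe_id = rownames(ds$lrr$lrr), ds$lrr$lrr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(lrr, file.path(out_dir, "lrr_matrix.tsv"))
  write_tsv(ds$lrr$annotation, file.path(out_dir, "probe_annotation.tsv"))
  write_tsv(ds$wgs_depth, file.path(out_dir, "wgs_depth.tsv"))
  write_tsv(ds$true_state, file.path(out_dir, "true_state.tsv"))

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_samples = config$n_samples,
    n_variants = config$n_variants,
    files = c("covariates.tsv", "dosages.tsv", "dosage_meta.tsv", "score.tsv",
              "lrr_matrix.tsv", "probe_annotation.tsv", "wgs_depth.tsv",
              "true_state.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

load_dataset <- function(data_dir) {
  p <- function(f) file.path(data_dir, f)
  dos <- read_tsv(p("dosages.tsv"))
  dmat <- as.matrix(dos[, -1, drop = FALSE])
  rownames(dmat) <- dos$sample_id
  lrr_df <- read_tsv(p("lrr_matrix.tsv"))
  lrr <- as.matrix(lrr_df[, -1, drop = FALSE])
  rownames(lrr) <- lrr_df$probe_id
  list(
    covariates = read_tsv(p("covariates.tsv")),
    genotypes = list(dosages = dmat, meta = read_tsv(p("dosage_meta.tsv")),
                     score = read_tsv(p("score.tsv"))),
    lrr = list(lrr = lrr, annotation = read_tsv(p("probe_annotation.tsv"))),
    wgs_depth = read_tsv(p("wgs_depth.tsv"))
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full LOY analysis on an in-memory dataset
#'
#' Executes the analysis chain: LOY calling from LRR (mLRRY, threshold,
#' percent of cells), baseline table, variant QC and PRS with quintile risk
#' groups, ANCOVA of the PRS distribution by LOY status, the per-SD and
#' risk-group logistic models (adjusted for age, current smoking and
#' current alcohol use), age-stratified risk-group models, the ROC/AUC
#' model comparison with DeLong's test, and (optionally) array-vs-WGS
#' concordance.
#'
#' @param dataset A list as produced by [simulate_dataset()] or
#'   [cmd_simulate()] + `load_dataset`; the `true_state` element is not
#'   used.
#' @param threshold `"reflected_null"` to estimate the calling threshold
#'   from the data, or a numeric fixed threshold (e.g. `-0.06`).
#' @param response_factor Array response factor for the mLRRY-to-fraction
#'   conversion.
#' @param with_wgs Run the WGS concordance stage.
#' @return A report list with elements `threshold`, `calls`,
#'   `prevalence_by_age`, `baseline`, `qc`, `prs`, `ancova`, `model_per_sd`,
#'   `model_risk_group`, `age_stratified`, `roc`, `concordance`, `counts`.
#' @export
analyze_loy_dataset <- function(dataset, threshold = "reflected_null",
                                response_factor = 0.46, with_wgs = TRUE) {
  calls <- run_stage("call-loy", {
    ml <- compute_mlrry(dataset$lrr$lrr, dataset$lrr$annotation)
    thr <- if (identical(threshold, "reflected_null")) {
      estimate_threshold(ml$mlrry)
    } else {
      fixed_threshold(threshold)
    }
    list(thr = thr, calls = call_loy(ml, thr, response_factor))
  })
  prev <- run_stage("call-loy", {
    prevalence_by_age(calls$calls, dataset$covariates)
  })
  baseline <- run_stage("baseline", {
    baseline_table(dataset$covariates, calls$calls)
  })
  prs <- run_stage("score", {
    meta <- variant_qc(dataset$genotypes$meta)
    aligned <- align_alleles(dataset$genotypes$score,
                             meta[meta$qc_pass, , drop = FALSE])
    raw <- compute_prs(dataset$genotypes$dosages, aligned)
    list(meta = meta, aligned = aligned,
         result = standardize_and_group(raw))
  })

  d <- merge(dataset$covariates, calls$calls[, c("sample_id", "is_loy")],
             by = "sample_id")
  d <- merge(d, prs$result[, c("sample_id", "z_score", "risk_group")],
             by = "sample_id")
  d <- d[order(d$sample_id), ]
  d$current_smoker <- encode_current(d$smoking)
  d$current_alcohol <- encode_current(d$alcohol)
  d$risk_group <- factor(d$risk_group, levels = c("low", "middle", "high"))

  assoc <- run_stage("associate", {
    list(
      ancova = ancova_prs(d$z_score, d$is_loy,
                          d[, c("age", "smoking", "alcohol")]),
      per_sd = fit_logistic(
        is_loy ~ z_score + age + current_smoker + current_alcohol, d),
      risk_group = fit_logistic(
        is_loy ~ risk_group + age + current_smoker + current_alcohol, d),
      strata = age_stratified_association(d)
    )
  })
  roc <- run_stage("associate", compare_prediction_models(d))
  concordance <- NULL
  if (with_wgs && !is.null(dataset$wgs_depth) && nrow(dataset$wgs_depth) > 0) {
    concordance <- run_stage("concordance", {
      wgs <- depth_log_ratio(dataset$wgs_depth)
      loy_concordance(calls$calls, wgs)
    })
  }
  list(
    threshold = calls$thr,
    calls = calls$calls,
    prevalence_by_age = prev,
    baseline = baseline,
    qc = attr(prs$meta, "qc_report"),
    variant_meta = prs$meta,
    prs = prs$result,
    ancova = assoc$ancova,
    model_per_sd = assoc$per_sd,
    model_risk_group = assoc$risk_group,
    age_stratified = assoc$strata,
    roc = roc,
    concordance = concordance,
    counts = list(
      n_samples = nrow(dataset$covariates),
      n_scored = sum(!is.na(calls$calls$mlrry)),
      n_loy = sum(calls$calls$is_loy, na.rm = TRUE),
      n_variants = nrow(dataset$genotypes$meta),
      n_variants_pass_qc = sum(prs$meta$qc_pass),
      n_variants_scored = nrow(prs$aligned)
    )
  )
}

assoc_rows <- function(model_name, fit) {
  data.frame(model = model_name, as.data.frame(fit),
             stringsAsFactors = FALSE)
}

#' Run the pipeline on a dataset directory and write the analysis report
#'
#' Reads the files written by [cmd_simulate()] (or equivalently formatted
#' real inputs), runs [analyze_loy_dataset()], and writes: per-sample LOY
#' calls and PRS tables, the variant QC report, the baseline table, every
#' association model as per-term rows, ROC and concordance JSON reports,
#' and a `report.json` summary with per-stage counts. Any stage failure
#' aborts with an error naming the stage.
#'
#' @param data_dir Directory holding the dataset files.
#' @param out_dir Output directory for the report files.
#' @param force Overwrite an existing non-empty output directory.
#' @inheritParams analyze_loy_dataset
#' @return Invisibly, the report list.
#' @export
cmd_run <- function(data_dir, out_dir, threshold = "reflected_null",
                    response_factor = 0.46, with_wgs = TRUE, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir,
         " exists and is non-empty; use force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- run_stage("load", load_dataset(data_dir))
  rep <- analyze_loy_dataset(dataset, threshold = threshold,
                             response_factor = response_factor,
                             with_wgs = with_wgs)

  write_tsv(rep$calls, file.path(out_dir, "loy_calls.tsv"))
  write_tsv(rep$prs, file.path(out_dir, "prs.tsv"))
  write_tsv(rep$qc, file.path(out_dir, "qc_report.tsv"))
  write_tsv(rep$prevalence_by_age, file.path(out_dir, "prevalence_by_age.tsv"))

  base_rows <- do.call(rbind, lapply(names(rep$baseline$categorical),
    function(v) {
      tab <- rep$baseline$categorical[[v]]
      data.frame(variable = v, tab, p_value = attr(tab, "p_value"),
                 stringsAsFactors = FALSE)
    }))
  write_tsv(base_rows, file.path(out_dir, "baseline_table.tsv"))

  models <- rbind(assoc_rows("per_sd", rep$model_per_sd),
                  assoc_rows("risk_group", rep$model_risk_group))
  for (st in names(rep$age_stratified)) {
    f <- rep$age_stratified[[st]]
    if (inherits(f, "assoc_result")) {
      models <- rbind(models, assoc_rows(paste0("age_", st), f))
    }
  }
  write_tsv(models, file.path(out_dir, "association_models.tsv"))

  jsonlite::write_json(
    list(threshold = unclass(rep$threshold),
         ancova_p = rep$ancova$p_value,
         auc_base = rep$roc$auc_base, auc_full = rep$roc$auc_full,
         delong = rep$roc$delong),
    file.path(out_dir, "roc_report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  if (!is.null(rep$concordance)) {
    jsonlite::write_json(rep$concordance,
                         file.path(out_dir, "concordance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  jsonlite::write_json(rep$counts, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rep)
}
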