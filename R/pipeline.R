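# End-to-end experiment: generate development and validation cohorts, fit the
# integrated GP classifier and regressor on the development cohort only,
# predict the held-out validation cohort, and evaluate against the
# additive-risk-score baseline and simulated clinicians.

stage_seed <- function(seed, k) {
  # product stays below 2^53, so the double arithmetic is exact
  as.integer(((as.numeric(seed) %% 94906265) * 22695477 + k) %% 2147483629)
}

#' Configuration of the full experiment
#'
#' @param dev_n,val_n development and validation cohort sizes.
#' @param seed single global seed; per-stage seeds are derived from it by a
#'   fixed mapping so stages can be rerun in isolation.
#' @param effect_sizes planted standardized effects, see [generator_config()].
#' @param missing_rate,artifact_rate,prevalence_day2,los_dispersion,severity_slope,mortality_rate
#'   generator settings shared by both cohorts, see [generator_config()].
#' @param apen approximate-entropy parameters ([apen_params()]).
#' @param kernel GP optimizer settings ([kernel_config()]); the default is
#'   sized for full cohorts (two restarts, 60 iterations).
#' @param folds stacking folds.
#' @param n_bins,hl_groups,bootstrap_B evaluation settings.
#' @param nurses,physicians clinician-simulation settings: lists with
#'   `noise_sd`, `delay_meanlog`, `delay_sdlog`, `delay_severity_effect`.
#' @param out_dir optional output directory; when given, cohorts, features,
#'   models, predictions, report tables and a manifest are written there.
#' @param quiet suppress per-stage log lines.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(dev_n = 461L, val_n = 499L, seed = 42L,
                              effect_sizes = c(risk_score = 0.9, age = 0.35,
                                               instability = 0.7,
                                               risk_x_instability = 0.3),
                              missing_rate = 0.055, artifact_rate = 1,
                              prevalence_day2 = 0.30, los_dispersion = 8,
                              severity_slope = 1.0, mortality_rate = 0.02,
                              apen = apen_params(),
                              kernel = kernel_config(restarts = 2L,
                                                     maxit = 60L,
                                                     seed = 1L),
                              folds = 5L, n_bins = 10L, hl_groups = 10L,
                              bootstrap_B = 1000L,
                              nurses = list(noise_sd = 0.8,
                                            delay_meanlog = log(4.2),
                                            delay_sdlog = 0.4,
                                            delay_severity_effect = 0.1),
                              physicians = list(noise_sd = 0.55,
                                                delay_meanlog = log(7.5),
                                                delay_sdlog = 0.45,
                                                delay_severity_effect = 0.1),
                              out_dir = NULL, quiet = FALSE) {
  structure(as.list(environment()), class = "experiment_config")
}

obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Run the full experiment
#'
#' Executes every stage with seeds derived from the global seed, enforcing
#' that no statistic, imputation constant or model parameter is ever fitted
#' on the validation cohort. Classification (probability of second-day
#' discharge) and regression (discrete day of discharge) are evaluated on the
#' full held-out cohort and on the clinician-answered sub-cohorts.
#'
#' @param config an [experiment_config()].
#' @return an `evaluation_report`: per-cohort classification and regression
#'   metric tables, pairwise model comparisons, reliability and prevalence
#'   tables, predictions, and a manifest of seeds and content hashes.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    stop_icu("invalid_config", "config must be an experiment_config")
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    if (!config$quiet)
      message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  gen_args <- config[c("missing_rate", "artifact_rate", "prevalence_day2",
                       "los_dispersion", "severity_slope", "mortality_rate")]
  gen_args$effect_sizes <- config$effect_sizes

  dev_cfg <- do.call(generator_config,
                     c(list(n_patients = config$dev_n,
                            seed = stage_seed(config$seed, 1L),
                            label = "development"), gen_args))
  val_cfg <- do.call(generator_config,
                     c(list(n_patients = config$val_n,
                            seed = stage_seed(config$seed, 2L),
                            label = "validation"), gen_args))
  dev <- generate_cohort(dev_cfg)
  val <- generate_cohort(val_cfg)
  log_stage("generate", "dev n=%d hash=%s; val n=%d hash=%s",
            config$dev_n, obj_hash(dev), config$val_n, obj_hash(val))

  stats <- fit_imputation_stats(dev, apen = config$apen)
  if (!identical(stats$fitted_on, "development"))
    stop_icu("leakage", "imputation statistics not fitted on the development cohort")
  feats_dev <- build_feature_matrices(dev, stats)
  feats_val <- build_feature_matrices(val, stats)
  for (f in feats_val)
    if (!identical(f$fitted_on, "development"))
      stop_icu("leakage", "validation features standardized with non-development stats")
  log_stage("extract", "5 categories, %d + %d patients",
            nrow(dev$admission), nrow(val$admission))

  y2_dev <- as.numeric(dev$outcomes$outcome_day == 2)
  yd_dev <- dev$outcomes$outcome_day
  cls <- fit_integrated_model(feats_dev, y2_dev, "classification",
                              config = config$kernel, folds = config$folds,
                              seed = stage_seed(config$seed, 3L))
  reg <- fit_integrated_model(feats_dev, yd_dev, "regression",
                              config = config$kernel, folds = config$folds,
                              seed = stage_seed(config$seed, 4L))
  log_stage("train", "classifier lml=%.2f, regressor lml=%.2f",
            cls$combiner$lml, reg$combiner$lml)

  gp_prob <- predict(cls, feats_val)$prob
  gp_day <- predict(reg, feats_val)$day
  base_prob <- score_to_probability(val$admission$risk_score, dev)
  base_day <- predict(fit_los_linear(dev), val$admission$risk_score)
  nurses <- do.call(simulate_clinician_predictions,
                    c(list(cohort = val,
                           seed = stage_seed(config$seed, 5L)),
                      config$nurses))
  physicians <- do.call(simulate_clinician_predictions,
                        c(list(cohort = val,
                               seed = stage_seed(config$seed, 6L)),
                          config$physicians))
  log_stage("predict", "GP, baseline, %d nurse and %d physician answers",
            sum(nurses$answered), sum(physicians$answered))

  y2_val <- as.numeric(val$outcomes$outcome_day == 2)
  yd_val <- val$outcomes$outcome_day
  cohorts <- list(
    validation = list(idx = rep(TRUE, length(y2_val)),
                      models = list(gp = list(prob = gp_prob, day = gp_day),
                                    risk_score = list(prob = base_prob,
                                                      day = base_day))),
    nurses_answered = list(idx = nurses$answered,
                           models = list(
                             gp = list(prob = gp_prob, day = gp_day),
                             risk_score = list(prob = base_prob, day = base_day),
                             nurses = list(prob = nurses$probability_day2,
                                           day = nurses$predicted_day))),
    physicians_answered = list(idx = physicians$answered,
                               models = list(
                                 gp = list(prob = gp_prob, day = gp_day),
                                 risk_score = list(prob = base_prob,
                                                   day = base_day),
                                 physicians = list(
                                   prob = physicians$probability_day2,
                                   day = physicians$predicted_day))))

  evaluation <- lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    idx <- co$idx
    if (sum(idx) < 10 || length(unique(y2_val[idx])) < 2)
      stop_icu("insufficient_data",
               "sub-cohort '%s' too small or one-class for evaluation", cn)
    cls_m <- lapply(co$models, function(m)
      classification_metrics(m$prob[idx], y2_val[idx],
                             n_bins = config$n_bins,
                             hl_groups = config$hl_groups))
    reg_m <- lapply(co$models, function(m)
      regression_metrics(yd_val[idx], m$day[idx]))
    others <- setdiff(names(co$models), "gp")
    comparisons <- lapply(setNames(others, others), function(om) {
      pm <- co$models[[om]]
      list(
        delong = tryCatch(
          delong_test(gp_prob[idx], pm$prob[idx], y2_val[idx]),
          icudischarge_degenerate_comparison = function(e) NULL),
        brier = bootstrap_brier_diff(gp_prob[idx], pm$prob[idx], y2_val[idx],
                                     B = config$bootstrap_B,
                                     seed = stage_seed(config$seed, 7L)),
        los = mann_whitney(gp_day[idx], pm$day[idx]),
        lpf = mann_whitney(lpf(yd_val[idx], gp_day[idx]),
                           lpf(yd_val[idx], pm$day[idx])),
        lpf_zero = chi_square_2x2(
          sum(gp_day[idx] == yd_val[idx]), sum(gp_day[idx] != yd_val[idx]),
          sum(pm$day[idx] == yd_val[idx]), sum(pm$day[idx] != yd_val[idx])))
    })
    list(n = sum(idx), classification = cls_m, regression = reg_m,
         comparisons = comparisons)
  })
  names(evaluation) <- names(cohorts)
  log_stage("evaluate", "validation aROC(GP)=%.3f BS=%.3f HL p=%.3f",
            evaluation$validation$classification$gp$aroc,
            evaluation$validation$classification$gp$brier,
            evaluation$validation$classification$gp$hl$p_value)

  predictions <- data.frame(
    patient_id = val$admission$patient_id,
    gp_probability_day2 = gp_prob, gp_predicted_day = gp_day,
    risk_score_probability_day2 = base_prob, risk_score_predicted_day = base_day,
    nurses_probability_day2 = nurses$probability_day2,
    nurses_predicted_day = nurses$predicted_day,
    physicians_probability_day2 = physicians$probability_day2,
    physicians_predicted_day = physicians$predicted_day,
    answered_nurses = nurses$answered,
    answered_physicians = physicians$answered,
    outcome_day = yd_val, stringsAsFactors = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("icudischarge")),
    global_seed = config$seed,
    stage_seeds = list(dev_cohort = stage_seed(config$seed, 1L),
                       val_cohort = stage_seed(config$seed, 2L),
                       classifier_folds = stage_seed(config$seed, 3L),
                       regressor_folds = stage_seed(config$seed, 4L),
                       nurses = stage_seed(config$seed, 5L),
                       physicians = stage_seed(config$seed, 6L),
                       bootstrap = stage_seed(config$seed, 7L)),
    hashes = list(dev_cohort = obj_hash(dev), val_cohort = obj_hash(val),
                  features_dev = obj_hash(lapply(feats_dev, `[[`, "values")),
                  features_val = obj_hash(lapply(feats_val, `[[`, "values")),
                  predictions = obj_hash(predictions)),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  report <- structure(list(evaluation = evaluation, predictions = predictions,
                           manifest = manifest, config = config,
                           models = list(classifier = cls, regressor = reg),
                           stats = stats),
                      class = "evaluation_report")
  if (!is.null(config$out_dir)) write_report_bundle(report, dev, val,
                                                    feats_dev, feats_val,
                                                    nurses, physicians)
  report
}

write_report_bundle <- function(report, dev, val, feats_dev, feats_val,
                                nurses, physicians) {
  out <- report$config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_cohort(dev, file.path(out, "cohort_development"))
  write_cohort(val, file.path(out, "cohort_validation"), clinicians = nurses)
  for (nm in names(feats_dev)) {
    for (side in c("development", "validation")) {
      f <- if (side == "development") feats_dev[[nm]] else feats_val[[nm]]
      base <- file.path(out, sprintf("features_%s_%s", side, nm))
      write.csv(data.frame(patient_id = rownames(f$values), f$values,
                           check.names = FALSE),
                paste0(base, ".csv"), row.names = FALSE)
      jsonlite::write_json(list(descriptors = f$descriptors,
                                standardization = f$standardization,
                                fitted_on = f$fitted_on),
                           paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
    }
  }
  save_gp_model(report$models$classifier$combiner,
                file.path(out, "model_classifier_combiner"))
  save_gp_model(report$models$regressor$combiner,
                file.path(out, "model_regressor_combiner"))
  write.csv(report$predictions, file.path(out, "predictions.csv"),
            row.names = FALSE)
  write.csv(classification_table(report), file.path(out, "classification_table.csv"),
            row.names = FALSE)
  write.csv(regression_table(report), file.path(out, "regression_table.csv"),
            row.names = FALSE)
  val_eval <- report$evaluation$validation
  write.csv(val_eval$classification$gp$decomposition$reliability_table,
            file.path(out, "reliability_gp_validation.csv"), row.names = FALSE)
  write.csv(val_eval$regression$gp$prevalence,
            file.path(out, "prevalence_gp_validation.csv"), row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  hashes <- tools::md5sum(files)
  jsonlite::write_json(as.list(setNames(unname(hashes),
                                        sub(paste0(out, "/?"), "", files))),
                       file.path(out, "file_hashes.json"), auto_unbox = TRUE)
  invisible(out)
}

fmt_miqr <- function(x) sprintf("%g (%g-%g)", x$median, x$p25, x$p75)
fmt_p <- function(p) {
  if (is.null(p) || is.na(p)) "X"
  else if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
}

#' Classification summary table of an experiment
#'
#' One row per (sub-cohort, metric), one column per model plus the
#' model-vs-GP comparison p-values; unavailable cells are printed as `"X"`.
#'
#' @param report an `evaluation_report`.
#' @return a data frame.
#' @export
classification_table <- function(report) {
  rows <- list()
  for (cn in names(report$evaluation)) {
    ev <- report$evaluation[[cn]]
    models <- names(ev$classification)
    for (metric in c("aROC", "Brier score", "Brier score scaled",
                     "Hosmer-Lemeshow p")) {
      cells <- vapply(models, function(m) {
        cm <- ev$classification[[m]]
        switch(metric,
               "aROC" = sprintf("%.3f", cm$aroc),
               "Brier score" = sprintf("%.3f", cm$brier),
               "Brier score scaled" = sprintf("%.1f%%", cm$brier_scaled),
               "Hosmer-Lemeshow p" = fmt_p(cm$hl$p_value))
      }, character(1))
      pvals <- vapply(models, function(m) {
        if (m == "gp") return("X")
        cmp <- ev$comparisons[[m]]
        switch(metric,
               "aROC" = if (is.null(cmp$delong)) "X" else fmt_p(cmp$delong$p_value),
               "Brier score" = fmt_p(cmp$brier$p_value),
               "X")
      }, character(1))
      row <- c(list(cohort = cn, n = ev$n, metric = metric),
               as.list(setNames(cells, models)),
               as.list(setNames(pvals, paste0(models, "_vs_gp_p"))))
      rows[[length(rows) + 1]] <- row
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_cols, names(r))
    r[miss] <- "X"
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  df[, setdiff(all_cols, "gp_vs_gp_p")]
}

#' Regression summary table of an experiment
#'
#' @inheritParams classification_table
#' @return a data frame mirroring the regression-task layout: median
#'   (P25-P75) LOS, median (P25-P75) LPF, patients with LPF = 0, RMSRE.
#' @export
regression_table <- function(report) {
  rows <- list()
  for (cn in names(report$evaluation)) {
    ev <- report$evaluation[[cn]]
    models <- names(ev$regression)
    actual <- fmt_miqr(ev$regression[[1]]$actual)
    for (metric in c("LOS median (P25-P75)", "LPF median (P25-P75)",
                     "Patients with LPF = 0", "RMSRE")) {
      cells <- vapply(models, function(m) {
        rm <- ev$regression[[m]]
        switch(metric,
               "LOS median (P25-P75)" = fmt_miqr(rm$predicted),
               "LPF median (P25-P75)" = sprintf("%g (%g-%g)",
                                                rm$lpf$median, rm$lpf$p25,
                                                rm$lpf$p75),
               "Patients with LPF = 0" = sprintf("%d (%.0f%%)", rm$lpf$n_zero,
                                                 rm$lpf$pct_zero),
               "RMSRE" = sprintf("%.3f", rm$rmsre))
      }, character(1))
      pvals <- vapply(models, function(m) {
        if (m == "gp") return("X")
        cmp <- ev$comparisons[[m]]
        switch(metric,
               "LOS median (P25-P75)" = fmt_p(cmp$los$p_value),
               "LPF median (P25-P75)" = fmt_p(cmp$lpf$p_value),
               "Patients with LPF = 0" = fmt_p(cmp$lpf_zero$p_value),
               "X")
      }, character(1))
      row <- c(list(cohort = cn, n = ev$n, metric = metric, actual = actual),
               as.list(setNames(cells, models)),
               as.list(setNames(pvals, paste0(models, "_vs_gp_p"))))
      rows[[length(rows) + 1]] <- row
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_cols, names(r))
    r[miss] <- "X"
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  df[, setdiff(all_cols, "gp_vs_gp_p")]
}

#' Render a human-readable experiment summary
#'
#' @param report an `evaluation_report`.
#' @return the printed lines, invisibly.
#' @export
render_report <- function(report) {
  lines <- c("== Second-day discharge (classification) ==",
             utils::capture.output(print(classification_table(report),
                                         row.names = FALSE)),
             "", "== Day of discharge (regression) ==",
             utils::capture.output(print(regression_table(report),
                                         row.names = FALSE)))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.evaluation_report <- function(x, ...) {
  v <- x$evaluation$validation
  cat(sprintf("<evaluation_report> validation n=%d: GP aROC %.3f, Brier %.3f, HL p %.3f; RMSRE %.3f\n",
              v$n, v$classification$gp$aroc, v$classification$gp$brier,
              v$classification$gp$hl$p_value, v$regression$gp$rmsre))
  cat("use render_report() for the full tables\n")
  invisible(x)
}
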