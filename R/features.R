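# Feature extraction: turns a cohort into the five per-category design
# matrices (admission, medication, laboratory, physiological, dynamic).
# All statistics used for imputation and standardization are fitted on the
# development cohort only and reused verbatim for any other cohort.

#' Approximate-entropy parameters
#'
#' @param m embedding dimension (positive integer).
#' @param r tolerance as a multiple of the series standard deviation.
#' @return an object of class `apen_params`.
#' @export
apen_params <- function(m = 2L, r = 0.2) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m))
    stop_icu("invalid_config", "m must be a positive integer")
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    stop_icu("invalid_config", "r must be a positive real")
  structure(list(m = as.integer(m), r = r), class = "apen_params")
}

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

FEATURE_CATEGORIES <- c("admission", "medication", "laboratory",
                        "physiological", "dynamic")
APEN_SIGNALS <- c("sap", "spo2", "hr")

#' Fit imputation and standardization statistics on a development cohort
#'
#' Computes everything later feature extraction needs: per-variable means of
#' observed numeric admission covariates, the configured "healthy" level for
#' each categorical covariate, the per-analyte and per-signal population
#' standard deviations (the former defines the laboratory trend tolerance),
#' the factor levels and drug/analyte lists fixing the design-matrix columns,
#' per-category feature-column means for imputing patient-level feature gaps,
#' and per-category standardization means/SDs.
#'
#' @param dev the development `icu_cohort`; statistics are never fitted on a
#'   validation cohort.
#' @param healthy_map named character vector mapping categorical admission
#'   covariates to the level representing a normal healthy condition.
#' @param apen an [apen_params()].
#' @return an object of class `imputation_stats`.
#' @export
fit_imputation_stats <- function(dev,
                                 healthy_map = c(rhythm = "sinus",
                                                 surgery_type = "OPCAB",
                                                 weekday = "Mon"),
                                 apen = apen_params()) {
  if (!inherits(dev, "icu_cohort") || nrow(dev$admission) == 0)
    stop_icu("invalid_config", "dev must be a nonempty icu_cohort")
  adm <- dev$admission
  num_vars <- c("age", "risk_score", "preop_hr", "preop_sbp", "repeat_surgery")
  means <- vapply(num_vars, function(v) {
    x <- adm[[v]]
    if (all(is.na(x)))
      stop_icu("invalid_config",
               "variable '%s' observed in zero patients of the development cohort", v)
    mean(x, na.rm = TRUE)
  }, numeric(1))
  cat_vars <- c("surgery_type", "weekday", "rhythm")
  levels_map <- lapply(setNames(cat_vars, cat_vars), function(v) {
    lev <- sort(unique(adm[[v]][!is.na(adm[[v]])]))
    healthy <- healthy_map[[v]]
    if (is.null(healthy))
      stop_icu("invalid_config", "no healthy level configured for '%s'", v)
    union(healthy, lev)  # healthy level first = reference
  })
  analytes <- LAB_ANALYTES[LAB_ANALYTES %in% unique(dev$labs$analyte)]
  if (length(analytes) < length(LAB_ANALYTES))
    stop_icu("invalid_config",
             "lab analyte '%s' observed in zero patients of the development cohort",
             setdiff(LAB_ANALYTES, analytes)[1])
  lab_sd <- vapply(setNames(analytes, analytes), function(a)
    pop_sd(dev$labs$value[dev$labs$analyte == a]), numeric(1))
  signal_sd <- vapply(dev$signals, function(m) pop_sd(as.vector(m)), numeric(1))
  drugs <- DRUG_CLASSES

  stats <- structure(list(
    fitted_on = dev$label, numeric_means = means, healthy_map = healthy_map,
    levels_map = levels_map, analytes = analytes, lab_sd = lab_sd,
    signal_sd = signal_sd, drugs = drugs, apen = apen,
    feature_means = NULL, standardization = NULL), class = "imputation_stats")

  # second pass: feature-column means (for patient-level gaps) and z-scoring
  stats$feature_means <- list()
  stats$standardization <- list()
  for (cat in FEATURE_CATEGORIES) {
    raw <- raw_feature_matrix(dev, cat, stats)
    cm <- colMeans(raw, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    stats$feature_means[[cat]] <- cm
    imp <- impute_columns(raw, cm)
    stats$standardization[[cat]] <-
      list(mean = colMeans(imp), sd = apply(imp, 2, pop_sd))
  }
  stats
}

impute_columns <- function(m, col_means) {
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- col_means[j]
  }
  m
}

#' Last value, count and trend of one analyte's repeated measurements
#'
#' The trend compares the last to the first observation: `0` ("same") if the
#' absolute change is within one development-cohort standard deviation of the
#' analyte, otherwise the sign of the change (`+1` increase, `-1` decrease).
#' A single observation has trend `0`.
#'
#' @param values ordered numeric observations within the 4-hour window.
#' @param sd the analyte's development-cohort standard deviation.
#' @return list with `value` (last observation), `count`, `trend` in
#'   `c(-1, 0, 1)`.
#' @export
lab_features <- function(values, sd) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop_icu("missing_analyte", "no observations: analyte takes the imputation path")
  delta <- values[length(values)] - values[1]
  trend <- if (abs(delta) <= sd) 0 else sign(delta)
  list(value = values[length(values)], count = length(values), trend = trend)
}

#' Peak-shaving artifact removal
#'
#' Single pass over a 240-minute series: observed values deviating more than
#' two (population) standard deviations from the series mean are marked
#' missing. Mean and SD are computed over the observed values before any
#' removal; a constant series (SD zero) is returned unchanged.
#'
#' @param series numeric vector of length 240, `NA` = missing.
#' @return the series with artifact slots set to `NA`.
#' @export
peak_shave <- function(series) {
  obs <- !is.na(series)
  if (sum(obs) < 2)
    stop_icu("unusable_series", "peak shaving needs at least 2 observed values")
  m <- mean(series[obs])
  s <- pop_sd(series)
  if (s > 0) series[obs & abs(series - m) > 2 * s] <- NA_real_
  series
}

#' Linear interpolation of missing values
#'
#' Interior gaps are linearly interpolated between the adjacent observed
#' values; leading and trailing gaps are filled with the nearest observed
#' value.
#'
#' @param series numeric vector with `NA` gaps, at least one observed value.
#' @return a complete series of the same length.
#' @export
interpolate_gaps <- function(series) {
  obs <- which(!is.na(series))
  if (length(obs) == 0)
    stop_icu("unusable_series", "cannot interpolate an all-missing series")
  if (length(obs) == length(series)) return(series)
  if (length(obs) == 1) return(rep(series[obs], length(series)))
  approx(obs, series[obs], xout = seq_along(series), method = "linear",
         rule = 2)$y
}

#' Windowed means and variances of a complete series
#'
#' Divides a 240-minute series into six contiguous 40-minute intervals and
#' returns the per-window mean and population variance.
#'
#' @param series complete numeric vector of length 240.
#' @param window window length in minutes (must divide the series length).
#' @return list with numeric vectors `mean` and `var`, one entry per window.
#' @export
window_stats <- function(series, window = 40L) {
  if (anyNA(series) || length(series) %% window != 0)
    stop_icu("contract_violation",
             "window_stats needs a complete series whose length is a multiple of the window")
  m <- matrix(series, nrow = window)
  mu <- colMeans(m)
  list(mean = mu, var = colMeans(m^2) - mu^2)
}

#' Approximate entropy of a time series
#'
#' Pincus ApEn(m, r, N): `Phi(m) - Phi(m+1)` where `Phi(k)` is the mean log
#' fraction of self-inclusive template matches of length `k` under Chebyshev
#' distance with absolute tolerance `r * SD(series)`. A constant series is
#' perfectly regular and returns 0 by convention.
#'
#' @param series complete numeric vector, length at least `m + 1`.
#' @param params an [apen_params()].
#' @return nonnegative scalar.
#' @export
approx_entropy <- function(series, params = apen_params()) {
  if (anyNA(series) || length(series) < params$m + 1)
    stop_icu("contract_violation",
             "approx_entropy needs a complete series of length >= m + 1")
  s <- pop_sd(series)
  if (s == 0) return(0)
  cpp_apen(series, params$m, params$r * s)
}

# Raw (unimputed, unstandardized) per-category matrix. NA cells mark
# patient-level gaps (missing analyte, unusable series) to be filled with
# development-cohort feature means.
raw_feature_matrix <- function(cohort, category, stats) {
  id <- cohort$admission$patient_id
  n <- length(id)
  switch(category,
    admission = {
      adm <- cohort$admission
      num <- sapply(names(stats$numeric_means), function(v) {
        x <- adm[[v]]
        x[is.na(x)] <- stats$numeric_means[[v]]
        as.numeric(x)
      })
      cats <- lapply(names(stats$levels_map), function(v) {
        lev <- stats$levels_map[[v]]
        x <- adm[[v]]
        x[is.na(x) | !(x %in% lev)] <- stats$healthy_map[[v]]
        ind <- sapply(lev[-1], function(l) as.numeric(x == l))
        colnames(ind) <- paste(v, lev[-1], sep = "_")
        ind
      })
      cbind(num, do.call(cbind, cats))
    },
    medication = {
      med <- cohort$medications
      out <- sapply(stats$drugs, function(d) {
        dose <- med$cumulative_dose[med$drug == d]
        v <- setNames(rep(0, n), id)  # drug never charted = none given
        v[med$patient_id[med$drug == d]] <- dose
        as.numeric(v)
      })
      colnames(out) <- paste0(stats$drugs, "_cumulative")
      out
    },
    laboratory = {
      out <- matrix(NA_real_, n, 3 * length(stats$analytes),
                    dimnames = list(id, paste(rep(stats$analytes, each = 3),
                                              c("value", "count", "trend"),
                                              sep = "_")))
      lab <- cohort$labs[order(cohort$labs$minute), ]
      for (a in stats$analytes) {
        da <- lab[lab$analyte == a, ]
        for (pid in unique(da$patient_id)) {
          lf <- lab_features(da$value[da$patient_id == pid], stats$lab_sd[[a]])
          out[pid, paste(a, c("value", "count", "trend"), sep = "_")] <-
            c(lf$value, lf$count, lf$trend)
        }
      }
      out
    },
    physiological = {
      sig <- sapply(names(cohort$signals), function(s) {
        m <- cohort$signals[[s]]
        nobs <- rowSums(!is.na(m))
        mu <- ifelse(nobs >= 2, rowMeans(m, na.rm = TRUE), NA_real_)
        v <- ifelse(nobs >= 2, rowMeans(m^2, na.rm = TRUE) - mu^2, NA_real_)
        cbind(mu, v)
      }, simplify = FALSE)
      sig <- do.call(cbind, sig)
      colnames(sig) <- paste(rep(names(cohort$signals), each = 2),
                             c("mean", "var"), sep = "_")
      fl <- cohort$fluids
      cum <- function(col) {
        v <- tapply(fl[[col]], fl$patient_id, sum)
        as.numeric(v[id])
      }
      cbind(sig, blood_loss_cumulative = cum("blood_loss_ml"),
            urine_cumulative = cum("urine_ml"))
    },
    dynamic = {
      cols <- c(unlist(lapply(names(cohort$signals), function(s)
        paste(s, rep(c("mean", "var"), each = 6), "w", 1:6, sep = "_"))),
        paste0("apen_", APEN_SIGNALS))
      out <- matrix(NA_real_, n, length(cols), dimnames = list(id, cols))
      for (s in names(cohort$signals)) {
        m <- cohort$signals[[s]]
        for (i in seq_len(n)) {
          series <- tryCatch(interpolate_gaps(peak_shave(m[i, ])),
                             icudischarge_unusable_series = function(e) NULL)
          if (is.null(series)) next  # patient-level gap, imputed later
          ws <- window_stats(series)
          out[i, paste(s, "mean", "w", 1:6, sep = "_")] <- ws$mean
          out[i, paste(s, "var", "w", 1:6, sep = "_")] <- ws$var
          if (s %in% APEN_SIGNALS)
            out[i, paste0("apen_", s)] <- approx_entropy(series, stats$apen)
        }
      }
      out
    },
    stop_icu("contract_violation", "unknown feature category '%s'", category))
}

#' Build one per-category feature matrix
#'
#' Applies imputation (development-cohort means for numeric gaps, configured
#' healthy levels for categorical gaps, development feature-column means for
#' patient-level gaps such as a never-measured analyte or an unusable signal)
#' and standardizes every column with the development-cohort mean and SD.
#'
#' @param cohort an `icu_cohort`.
#' @param category one of `"admission"`, `"medication"`, `"laboratory"`,
#'   `"physiological"`, `"dynamic"`.
#' @param stats an [fit_imputation_stats()] result (development cohort only).
#' @return an object of class `feature_matrix`: list with the numeric
#'   `values` matrix (patients x columns, no missing values), the `category`,
#'   per-column `descriptors`, the `standardization` stats applied, and
#'   `fitted_on` provenance.
#' @export
build_feature_matrix <- function(cohort, category, stats) {
  if (!category %in% FEATURE_CATEGORIES)
    stop_icu("contract_violation", "unknown feature category '%s'", category)
  if (!inherits(stats, "imputation_stats"))
    stop_icu("invalid_config", "stats must come from fit_imputation_stats()")
  raw <- raw_feature_matrix(cohort, category, stats)
  imp <- impute_columns(raw, stats$feature_means[[category]])
  st <- stats$standardization[[category]]
  sd_safe <- ifelse(st$sd > 0, st$sd, 1)
  values <- sweep(sweep(imp, 2, st$mean), 2, sd_safe, "/")
  rownames(values) <- cohort$admission$patient_id
  desc <- parse_descriptors(colnames(values), category)
  structure(list(values = values, category = category, descriptors = desc,
                 standardization = st, fitted_on = stats$fitted_on),
            class = "feature_matrix")
}

parse_descriptors <- function(cols, category) {
  stat <- rep("value", length(cols))
  window <- rep(NA_integer_, length(cols))
  stat[grepl("_count$", cols)] <- "count"
  stat[grepl("_trend$", cols)] <- "trend"
  stat[grepl("_cumulative$", cols)] <- "cumulative"
  stat[grepl("_mean(_w_[1-6])?$", cols)] <- "mean"
  stat[grepl("_var(_w_[1-6])?$", cols)] <- "variance"
  stat[grepl("^apen_", cols)] <- "apen"
  has_w <- grepl("_w_[1-6]$", cols)
  window[has_w] <- as.integer(sub("_w_", "",
                                  regmatches(cols, regexpr("_w_[1-6]$", cols))))
  data.frame(column = cols, category = category, statistic = stat,
             window = window, stringsAsFactors = FALSE)
}

#' Build all five per-category feature matrices
#'
#' @inheritParams build_feature_matrix
#' @return named list of five `feature_matrix` objects.
#' @export
build_feature_matrices <- function(cohort, stats) {
  lapply(setNames(FEATURE_CATEGORIES, FEATURE_CATEGORIES),
         function(cat) build_feature_matrix(cohort, cat, stats))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> category '%s': %d patients x %d columns (fitted on '%s')\n",
              x$category, nrow(x$values), ncol(x$values), x$fitted_on))
  invisible(x)
}
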