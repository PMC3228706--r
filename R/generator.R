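# Synthetic PDMS-style cohort generator.
#
# One latent severity score per patient drives everything downstream: the
# discrete day of ICU discharge, vasoactive drug use, lactate kinetics, urine
# output, and the stability of the per-minute monitor signals. Admission
# covariates (additive risk score, age) and a latent "instability" factor are
# the planted predictors; their standardized weights live in
# `effect_sizes`, so a cohort with all-zero effects carries no signal at all.

SIGNAL_NAMES <- c("sap", "spo2", "hr", "temp", "spap")
LAB_ANALYTES <- c("lactate", "hemoglobin", "glucose", "creatinine", "potassium")
DRUG_CLASSES <- c("norepinephrine", "propofol", "insulin", "crystalloid", "packed_cells")

#' Configuration of the synthetic cohort generator
#'
#' Assembles and validates the parameters of the synthetic ICU cohort
#' generator. The defaults are calibrated so that a generated cohort
#' reproduces the marginal structure of a scheduled cardiac-surgery ICU
#' population: discrete length of stay with median (P25-P75) of 3 (2-5) days,
#' about 30% of patients discharged on the day after surgery, about 2% ICU
#' mortality, an additive operative risk score with median (P25-P75) 5 (3-7),
#' and 5-6% missing monitor data.
#'
#' @param n_patients number of patients (at least 2).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param missing_rate fraction of per-minute signal slots (and of selected
#'   admission/laboratory entries) set missing completely at random.
#' @param artifact_rate expected number of spike artifacts per signal per
#'   4-hour series (Poisson).
#' @param prevalence_day2 target marginal probability of discharge on day 2;
#'   the negative-binomial intercept is calibrated by root finding so the
#'   realized cohort matches it in expectation.
#' @param los_dispersion size parameter of the negative-binomial day count
#'   (larger = less conditional dispersion around the severity-driven mean).
#' @param severity_slope slope of the log-mean of the day count in the
#'   standardized latent severity.
#' @param effect_sizes named numeric vector of standardized planted effects on
#'   latent severity; recognised names are `risk_score`, `age`, `instability`
#'   and `risk_x_instability`. Zero everywhere yields a signal-free cohort.
#' @param residual_sd standard deviation of the severity component not
#'   explained by any planted predictor.
#' @param mortality_rate target marginal ICU mortality (death is coded as
#'   discharge on the day of death).
#' @param label cohort label, e.g. `"development"` or `"validation"`.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients,
                             seed = 1L,
                             missing_rate = 0.055,
                             artifact_rate = 1,
                             prevalence_day2 = 0.30,
                             los_dispersion = 8,
                             severity_slope = 1.0,
                             effect_sizes = c(risk_score = 0.9, age = 0.35,
                                              instability = 0.7,
                                              risk_x_instability = 0.3),
                             residual_sd = 0.5,
                             mortality_rate = 0.02,
                             label = "cohort") {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 2)
    stop_icu("invalid_config", "n_patients must be a single integer >= 2")
  for (nm in c("missing_rate", "prevalence_day2", "mortality_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_icu("invalid_config", "%s must lie in [0, 1]", nm)
  }
  if (prevalence_day2 <= 0 || prevalence_day2 >= 1)
    stop_icu("invalid_config", "prevalence_day2 must lie strictly in (0, 1)")
  if (artifact_rate < 0 || los_dispersion <= 0 || residual_sd < 0)
    stop_icu("invalid_config", "rates and dispersions must be nonnegative")
  if (any(!is.finite(effect_sizes)))
    stop_icu("invalid_config", "effect_sizes must be finite")
  es <- c(risk_score = 0, age = 0, instability = 0, risk_x_instability = 0)
  es[names(effect_sizes)] <- effect_sizes
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 missing_rate = missing_rate, artifact_rate = artifact_rate,
                 prevalence_day2 = prevalence_day2,
                 los_dispersion = los_dispersion,
                 severity_slope = severity_slope,
                 effect_sizes = es, residual_sd = residual_sd,
                 mortality_rate = mortality_rate, label = label),
            class = "generator_config")
}

round_half_up <- function(x) floor(x + 0.5)

# Deterministic reference sample from the latent-severity law (fixed internal
# seed, cohort RNG stream restored afterwards). Calibrating the outcome
# intercepts and the severity standardization against this shared reference
# -- rather than per cohort -- makes every cohort an iid sample from one
# population, so a model fitted on a development cohort faces the same
# conditional law in a validation cohort.
severity_reference <- function(es, residual_sd, m = 2e5) {
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(814223L)
  age <- pmin(90, pmax(19, round_half_up(rnorm(m, 67, 11))))
  risk <- rnbinom(m, size = 8, mu = 5)
  zr <- (risk - 5) / sqrt(5 + 25 / 8)
  za <- (age - 67) / 11
  zi <- rnorm(m)
  sys <- es["risk_score"] * zr + es["age"] * za + es["instability"] * zi +
    es["risk_x_instability"] * zr * zi
  list(sys_mean = mean(sys), sys_sd = sd(sys),
       total = sys + residual_sd * rnorm(m))
}

# stationary AR(1) matrix (n patients x 240 minutes), per-patient phi and sd
ar1_matrix <- function(n, baseline, phi, innov_sd, n_min = 240L) {
  x <- matrix(0, n, n_min)
  x[, 1] <- rnorm(n, 0, innov_sd / sqrt(1 - phi^2))
  for (t in 2:n_min) x[, t] <- phi * x[, t - 1] + rnorm(n, 0, innov_sd)
  x + baseline
}

#' Generate a synthetic ICU cohort
#'
#' Draws a complete seeded cohort: admission covariates, cumulative
#' medications over the first 4 hours, repeated timestamped laboratory
#' results, five per-minute monitor signals of 240 minutes each (systolic
#' arterial pressure, SpO2, heart rate, central temperature, systolic
#' pulmonary artery pressure), hourly fluid records, and the discrete day of
#' ICU discharge (day 2 is the earliest possible; ICU death is coded as
#' discharge on the day of death).
#'
#' The day of discharge is `2 + NB(size, mu)` with `log(mu)` linear in the
#' standardized latent severity; the intercept is calibrated at generation
#' time so the expected day-2 discharge fraction equals
#' `config$prevalence_day2`. Signals are stationary AR(1) series whose
#' innovation variance and irregularity increase with the latent instability
#' factor; spike artifacts and completely-at-random missingness are then
#' applied.
#'
#' @param config a [generator_config()].
#' @return an object of class `icu_cohort`: a list with data frames
#'   `admission`, `medications`, `labs`, `fluids`, `outcomes`, a list
#'   `signals` of five n x 240 matrices, latent truth in `latent`, and the
#'   originating config.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_icu("invalid_config", "config must be a generator_config")
  set.seed(config$seed)
  n <- config$n_patients
  es <- config$effect_sizes
  id <- sprintf("P%05d", seq_len(n))

  ## admission covariates -----------------------------------------------------
  age <- pmin(90, pmax(19, round_half_up(rnorm(n, 67, 11))))
  risk_score <- rnbinom(n, size = 8, mu = 5)        # additive operative risk
  surgery_type <- sample(c("OPCAB", "valve", "other"), n, replace = TRUE,
                         prob = c(0.385, 0.57, 0.045))
  weekday <- sample(c("Mon", "Tue", "Wed", "Thu", "Fri"), n, replace = TRUE)
  rhythm <- sample(c("sinus", "afib"), n, replace = TRUE, prob = c(0.86, 0.14))
  repeat_surgery <- rbinom(n, 1, 0.08)
  preop_hr <- round_half_up(rnorm(n, 75, 12))
  preop_sbp <- round_half_up(rnorm(n, 135, 18))

  ## latent severity ----------------------------------------------------------
  z_risk <- (risk_score - 5) / sqrt(5 + 25 / 8)
  z_age <- (age - 67) / 11
  z_inst <- rnorm(n)
  # systematic component: what the planted predictors (and hence every
  # observable channel) carry; the residual is outcome-side noise no model
  # can see, so all-zero effect sizes give a genuinely signal-free cohort
  sev_sys <- es["risk_score"] * z_risk + es["age"] * z_age +
    es["instability"] * z_inst + es["risk_x_instability"] * z_risk * z_inst
  ref <- severity_reference(es, config$residual_sd)
  ref_sd <- sd(ref$total)
  sev_obs <- if (ref$sys_sd > 0) (sev_sys - ref$sys_mean) / ref$sys_sd
             else sev_sys * 0
  severity <- if (ref_sd > 0)
    (sev_sys + config$residual_sd * rnorm(n) - mean(ref$total)) / ref_sd
  else sev_sys * 0
  ref_std <- if (ref_sd > 0) (ref$total - mean(ref$total)) / ref_sd
             else ref$total * 0

  ## outcome: day of discharge ------------------------------------------------
  th <- config$los_dispersion
  g <- config$severity_slope
  c0 <- uniroot(function(c0)
    mean(dnbinom(0, size = th, mu = exp(c0 + g * ref_std))) -
      config$prevalence_day2, c(-10, 10))$root
  outcome_day <- 2L + rnbinom(n, size = th, mu = exp(c0 + g * severity))
  died <- if (config$mortality_rate > 0) {
    a0 <- uniroot(function(a)
      mean(plogis(a + 1.5 * ref_std)) - config$mortality_rate, c(-20, 10))$root
    rbinom(n, 1, plogis(a0 + 1.5 * severity))
  } else integer(n)

  ## medications (cumulative, first 4 h) --------------------------------------
  norepi <- round(exp(rnorm(n, 0.6 + 0.8 * sev_obs, 0.5)), 1)  # mg cumulative
  propofol <- round_half_up(pmax(0, rnorm(n, 550, 150)))        # mg
  insulin <- round(pmax(0, rnorm(n, 2 + 1.2 * sev_obs, 2)), 1) # U
  crystalloid <- round_half_up(pmax(0, rnorm(n, 800 + 100 * sev_obs, 200)))
  packed_cells <- rpois(n, 0.2 * exp(0.5 * sev_obs))           # units
  medications <- data.frame(
    patient_id = rep(id, times = 5),
    drug = rep(DRUG_CLASSES, each = n),
    cumulative_dose = c(norepi, propofol, insulin, crystalloid, packed_cells),
    units = rep(c("mg", "mg", "U", "mL", "units"), each = n),
    stringsAsFactors = FALSE)

  ## laboratory results (repeated, timestamped) -------------------------------
  lab_base <- list(
    lactate    = list(mu = 1.3 * exp(0.30 * sev_obs), noise = 0.12,
                      drift = 0.30 * sev_obs, digits = 2),
    hemoglobin = list(mu = rnorm(n, 10.5, 1.2) - 0.3 * sev_obs, noise = 0.25,
                      drift = -0.04 - 0.02 * sev_obs, digits = 1),
    glucose    = list(mu = rnorm(n, 135, 22) + 8 * sev_obs, noise = 6,
                      drift = 0.05 * sev_obs, digits = 0),
    creatinine = list(mu = pmax(0.4, rnorm(n, 1.0, 0.25) + 0.10 * sev_obs),
                      noise = 0.05, drift = 0.04 * sev_obs, digits = 2),
    potassium  = list(mu = rnorm(n, 4.2, 0.4), noise = 0.12, drift = 0,
                      digits = 1))
  lab_counts <- 1L + rpois(n * length(LAB_ANALYTES),
                           pmax(0.2, 1.2 + 0.4 * rep(sev_obs, length(LAB_ANALYTES))))
  labs_list <- vector("list", length(LAB_ANALYTES))
  for (a in seq_along(LAB_ANALYTES)) {
    an <- LAB_ANALYTES[a]
    par <- lab_base[[an]]
    cnt <- lab_counts[(a - 1) * n + seq_len(n)]
    minute <- lapply(cnt, function(k) sort(sample(5:235, k)))
    pid <- rep(id, times = cnt)
    mins <- unlist(minute)
    sev_rep <- rep(seq_len(n), times = cnt)
    mu <- rep(par$mu, times = cnt)
    drift <- rep(par$drift, length.out = n)[sev_rep]
    val <- mu * (1 + drift * mins / 240) + rnorm(length(mins), 0, par$noise)
    labs_list[[a]] <- data.frame(patient_id = pid, analyte = an,
                                 minute = mins,
                                 value = round(val, par$digits),
                                 stringsAsFactors = FALSE)
  }
  labs <- do.call(rbind, labs_list)
  # whole-analyte dropout exercises the imputation path
  if (config$missing_rate > 0) {
    drop <- matrix(runif(n * length(LAB_ANALYTES)) < config$missing_rate, n)
    keep_key <- paste(rep(id, length(LAB_ANALYTES)),
                      rep(LAB_ANALYTES, each = n))[!as.vector(drop)]
    labs <- labs[paste(labs$patient_id, labs$analyte) %in% keep_key, ]
  }
  rownames(labs) <- NULL

  ## per-minute monitor signals -----------------------------------------------
  instab <- plogis(z_inst)                       # in (0,1)
  phi <- 0.92 - 0.25 * instab                    # irregularity channel
  scale_sd <- exp(0.35 * z_inst)                 # variance channel
  base <- list(
    sap  = list(b = rnorm(n, 124, 10) - 4 * sev_obs, sd = 3.5),
    spo2 = list(b = pmin(99.5, rnorm(n, 97.3, 1.0) - 0.5 * pmax(sev_obs, 0)),
                sd = 0.55),
    hr   = list(b = rnorm(n, 82, 9) + 4 * sev_obs, sd = 2.2),
    temp = list(b = rnorm(n, 36.6, 0.4) + 0.15 * sev_obs, sd = 0.045),
    spap = list(b = rnorm(n, 28, 5) + 2.5 * sev_obs, sd = 1.6))
  signals <- list()
  for (s in SIGNAL_NAMES) {
    x <- ar1_matrix(n, base[[s]]$b, phi, base[[s]]$sd * scale_sd)
    if (s == "spo2") x <- pmin(x, 100)
    # spike artifacts: +/- (4-8) series SD at random minutes
    k <- rpois(n, config$artifact_rate)
    for (i in which(k > 0)) {
      at <- sample.int(240, k[i])
      ssd_i <- sd(x[i, ])
      x[i, at] <- x[i, at] +
        sample(c(-1, 1), k[i], replace = TRUE) * runif(k[i], 4, 8) * ssd_i
    }
    if (config$missing_rate > 0)
      x[matrix(runif(n * 240) < config$missing_rate, n)] <- NA_real_
    dimnames(x) <- list(id, NULL)
    signals[[s]] <- round(x, 2)
  }

  ## fluids (hourly) ----------------------------------------------------------
  fl_mean <- 40 * exp(0.30 * sev_obs)
  ur_mean <- 120 * exp(-0.35 * sev_obs)
  fluids <- data.frame(
    patient_id = rep(id, each = 4), hour = rep(1:4, n),
    blood_loss_ml = round_half_up(rgamma(4 * n, shape = 4,
                                         rate = 4 / rep(fl_mean, each = 4))),
    urine_ml = round_half_up(rgamma(4 * n, shape = 6,
                                    rate = 6 / rep(ur_mean, each = 4))),
    stringsAsFactors = FALSE)

  ## admission-level missingness (numeric + categorical imputation paths) -----
  if (config$missing_rate > 0) {
    preop_hr[runif(n) < config$missing_rate] <- NA
    preop_sbp[runif(n) < config$missing_rate] <- NA
    rhythm[runif(n) < config$missing_rate] <- NA
  }

  admission <- data.frame(
    patient_id = id, age = age, risk_score = risk_score,
    surgery_type = surgery_type, weekday = weekday, rhythm = rhythm,
    repeat_surgery = repeat_surgery, preop_hr = preop_hr,
    preop_sbp = preop_sbp, stringsAsFactors = FALSE)
  outcomes <- data.frame(patient_id = id, outcome_day = outcome_day,
                         died = died, stringsAsFactors = FALSE)

  structure(list(admission = admission, medications = medications,
                 labs = labs, signals = signals, fluids = fluids,
                 outcomes = outcomes,
                 latent = data.frame(patient_id = id, severity = severity,
                                     severity_observable = sev_obs,
                                     instability = z_inst,
                                     stringsAsFactors = FALSE),
                 label = config$label, config = config),
            class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf("<icu_cohort> '%s': %d patients, %d signals x 240 min, %s lab rows\n",
              x$label, nrow(x$admission), length(x$signals), nrow(x$labs)))
  cat(sprintf("  day of discharge: median %s (IQR %s-%s), day-2 fraction %.3f, died %.3f\n",
              median(x$outcomes$outcome_day),
              quantile(x$outcomes$outcome_day, 0.25),
              quantile(x$outcomes$outcome_day, 0.75),
              mean(x$outcomes$outcome_day == 2), mean(x$outcomes$died)))
  invisible(x)
}

#' Fraction of missing entries in the monitor signals
#'
#' @param cohort an `icu_cohort`.
#' @return fraction of the n x 240 x 5 signal slots that are missing.
#' @export
missing_fraction <- function(cohort) {
  miss <- vapply(cohort$signals, function(m) sum(is.na(m)), numeric(1))
  sum(miss) / (length(cohort$signals) * prod(dim(cohort$signals[[1]])))
}

#' Simulate clinician discharge predictions
#'
#' Emulates bedside nurses or physicians answering, some hours after
#' admission, (i) the probability that the patient leaves the ICU on the day
#' after surgery and (ii) the predicted discrete day of discharge. Answers are
#' the true outcome corrupted by seeded noise; each clinician answers after a
#' lognormal response delay that may grow with patient severity (harder
#' patients postponed), and answers arriving after `answer_window_h` hours are
#' recorded as absent, which creates the answered sub-cohort.
#'
#' @param cohort an `icu_cohort`.
#' @param noise_sd standard deviation of the noise added to the true binary
#'   outcome on the probability scale (and, scaled by 2, to the true day).
#' @param delay_meanlog,delay_sdlog lognormal parameters of the response delay
#'   in hours.
#' @param delay_severity_effect multiplicative log-scale effect of latent
#'   severity on the delay (positive = sicker patients answered later).
#' @param answer_window_h answers later than this many hours are discarded.
#' @param seed integer seed (defaults to a fixed offset of the cohort seed).
#' @return a data frame of class `clinician_predictions` with columns
#'   `patient_id`, `probability_day2`, `predicted_day`, `response_delay_h`,
#'   `answered`; predictions are `NA` where unanswered.
#' @export
simulate_clinician_predictions <- function(cohort, noise_sd = 0.35,
                                           delay_meanlog = log(4.5),
                                           delay_sdlog = 0.35,
                                           delay_severity_effect = 0,
                                           answer_window_h = 6,
                                           seed = NULL) {
  if (!inherits(cohort, "icu_cohort"))
    stop_icu("invalid_config", "cohort must be an icu_cohort")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_icu("invalid_config", "noise_sd must be a nonnegative number")
  if (is.null(seed)) seed <- (cohort$config$seed * 7L + 101L) %% .Machine$integer.max
  set.seed(seed)
  n <- nrow(cohort$outcomes)
  y <- as.numeric(cohort$outcomes$outcome_day == 2)
  delay <- exp(rnorm(n, delay_meanlog, delay_sdlog) +
                 delay_severity_effect * cohort$latent$severity)
  prob <- pmin(1, pmax(0, y + rnorm(n, 0, noise_sd)))
  day <- pmax(2, round_half_up(cohort$outcomes$outcome_day +
                                 rnorm(n, 0, 2 * noise_sd)))
  answered <- delay <= answer_window_h
  prob[!answered] <- NA_real_
  day[!answered] <- NA_real_
  out <- data.frame(patient_id = cohort$outcomes$patient_id,
                    probability_day2 = prob, predicted_day = as.integer(day),
                    response_delay_h = delay, answered = answered,
                    stringsAsFactors = FALSE)
  class(out) <- c("clinician_predictions", "data.frame")
  out
}
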