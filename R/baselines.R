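# Additive-risk-score baseline: the comparator an ICU would reach for
# without a learned model. The score is mapped to a second-day-discharge
# probability by rank normalization on the development cohort, and to a
# discrete day of discharge by ordinary least squares of LOS on the score.

#' Map additive risk scores to second-day-discharge probabilities
#'
#' A monotone non-increasing mapping fitted on the development cohort: the
#' probability assigned to score `s` is one minus the mid-rank empirical
#' cumulative fraction of development scores below `s`. Higher operative risk
#' thus means lower discharge probability; equal scores get equal
#' probabilities. If the development scores are constant the mapping is
#' degenerate and every patient receives the development day-2 prevalence
#' (with a warning).
#'
#' @param scores nonnegative integer additive risk scores to convert.
#' @param dev the development `icu_cohort` (scores and outcomes are taken
#'   from it).
#' @return probabilities in `[0, 1]`.
#' @export
score_to_probability <- function(scores, dev) {
  if (!inherits(dev, "icu_cohort"))
    stop_icu("invalid_config", "dev must be an icu_cohort")
  ds <- dev$admission$risk_score
  if (length(unique(ds)) < 2) {
    warn_icu("degenerate_baseline",
             "development risk scores are constant; using prevalence")
    return(rep(mean(dev$outcomes$outcome_day == 2), length(scores)))
  }
  n <- length(ds)
  vapply(scores, function(s)
    1 - (sum(ds < s) + 0.5 * sum(ds == s)) / n, numeric(1))
}

#' Linear LOS-on-score baseline
#'
#' Ordinary least squares of the discrete day of discharge on the additive
#' risk score, fitted on the development cohort; predictions are rounded to
#' the nearest integer day and clipped at day 2.
#'
#' @param dev the development `icu_cohort`.
#' @return an object of class `linear_los_model` with `intercept` and
#'   `slope`.
#' @export
fit_los_linear <- function(dev) {
  if (!inherits(dev, "icu_cohort") || nrow(dev$admission) == 0)
    stop_icu("invalid_config", "dev must be a nonempty icu_cohort")
  s <- dev$admission$risk_score
  if (var(s) == 0)
    stop_icu("degenerate_baseline", "development risk scores have zero variance")
  fit <- lm(dev$outcomes$outcome_day ~ s)
  structure(list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
                 fitted_on = dev$label),
            class = "linear_los_model")
}

#' @param object a `linear_los_model`.
#' @param newdata numeric vector of additive risk scores.
#' @param ... unused.
#' @rdname fit_los_linear
#' @export
predict.linear_los_model <- function(object, newdata, ...) {
  pmax(2L, as.integer(floor(object$intercept + object$slope * newdata + 0.5)))
}
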