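# Integration of the five per-category GP submodels by stacked
# generalization: a combiner GP of the same task kind is fitted on
# out-of-fold submodel predictions, which keeps the combiner's training
# inputs honest (no submodel ever predicts its own training fold).

#' Fit the integrated (stacked) per-category GP model
#'
#' For each feature category a GP submodel is fitted per task. K-fold
#' out-of-fold submodel predictions form a patients x categories input table
#' on which a combiner GP of the same kind is fitted; for prediction, the
#' submodels are refitted on all development data and their outputs are fed
#' to the combiner.
#'
#' @param features named list of `feature_matrix` objects (or plain numeric
#'   matrices), one per category; all for the same patients.
#' @param y target: binary second-day-discharge labels (classification) or
#'   integer outcome days `>= 2` (regression).
#' @param task `"classification"` or `"regression"`.
#' @param config a [kernel_config()] used for submodels and combiner.
#' @param folds number of stacking folds.
#' @param seed seed of the fold assignment.
#' @param categories category names required to be present.
#' @return an object of class `integrated_model`.
#' @export
fit_integrated_model <- function(features, y,
                                 task = c("classification", "regression"),
                                 config = kernel_config(), folds = 5L,
                                 seed = 1L,
                                 categories = names(features)) {
  task <- match.arg(task)
  if (is.null(names(features)) || !all(categories %in% names(features)))
    stop_icu("invalid_config", "missing feature category: %s",
             paste(setdiff(categories, names(features)), collapse = ", "))
  mats <- lapply(features[categories], function(f)
    if (inherits(f, "feature_matrix")) f$values else as.matrix(f))
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 1L) != n) || length(y) != n)
    stop_icu("contract_violation", "all categories must cover the same patients")
  if (folds < 2 || folds > n)
    stop_icu("invalid_config", "folds must lie in [2, n]")

  fit_one <- function(X, yy) {
    if (task == "classification") fit_gp_classification(X, yy, config)
    else fit_gp_regression(X, yy, config, transform = "log_day")
  }
  # regression submodels are stacked on their working (log-day) scale, where
  # errors stay additive; the exp back-transform happens only after the
  # combiner
  predict_one <- function(model, X) {
    p <- predict(model, X)
    if (task == "classification") p$prob else p$mean
  }

  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  Z <- matrix(NA_real_, n, length(categories),
              dimnames = list(rownames(mats[[1]]), categories))
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    for (cat in categories) {
      sub <- fit_one(mats[[cat]][!hold, , drop = FALSE], y[!hold])
      Z[hold, cat] <- predict_one(sub, mats[[cat]][hold, , drop = FALSE])
    }
  }

  # combiner inputs stay on their native scale (probabilities / days):
  # out-of-fold and refit submodel outputs then share a common geometry
  z_mean <- rep(0, ncol(Z))
  z_sd <- rep(1, ncol(Z))
  Zs <- sweep(sweep(Z, 2, z_mean), 2, z_sd, "/")
  combiner <- fit_one(Zs, y)
  submodels <- lapply(categories, function(cat) fit_one(mats[[cat]], y))
  names(submodels) <- categories

  structure(list(task = task, submodels = submodels, combiner = combiner,
                 categories = categories, fold_id = fold_id, seed = seed,
                 oof = Z, z_mean = z_mean, z_sd = z_sd, config = config),
            class = "integrated_model")
}

#' Predict from an integrated model
#'
#' @param object an `integrated_model`.
#' @param newdata named list of feature matrices for the same categories the
#'   model was fitted on.
#' @param ... unused.
#' @return data frame with per-category submodel outputs (class probabilities
#'   for classification, log-day latent means for regression) plus the
#'   integrated prediction: `prob` (classification) or `day_cont`/`day`
#'   (regression).
#' @export
predict.integrated_model <- function(object, newdata, ...) {
  absent <- setdiff(object$categories, names(newdata))
  if (length(absent) > 0)
    stop_icu("invalid_config", "newdata must contain every fitted category (missing: %s)",
             paste(absent, collapse = ", "))
  mats <- lapply(newdata[object$categories], function(f)
    if (inherits(f, "feature_matrix")) f$values else as.matrix(f))
  Z <- vapply(object$categories, function(cat) {
    p <- predict(object$submodels[[cat]], mats[[cat]])
    if (object$task == "classification") p$prob else p$mean
  }, numeric(nrow(mats[[1]])))
  Z <- matrix(Z, ncol = length(object$categories),
              dimnames = list(rownames(mats[[1]]), object$categories))
  Zs <- sweep(sweep(Z, 2, object$z_mean), 2, object$z_sd, "/")
  out <- as.data.frame(Z)
  comb <- predict(object$combiner, Zs)
  if (object$task == "classification") out$prob <- comb$prob
  else { out$day_cont <- comb$day_cont; out$day <- comb$day }
  out
}

#' Predicted discrete day of discharge
#'
#' Maps the integrated regression model's continuous prediction back to the
#' discrete day scale: inverse log transform, round to the nearest integer,
#' clip at day 2 (no patient leaves on the surgery day).
#'
#' @param model an `integrated_model` of task `"regression"` (or a
#'   regression `gp_model`).
#' @param newdata features as in [predict.integrated_model()].
#' @return integer vector of predicted days, all `>= 2`.
#' @export
predict_day_of_discharge <- function(model, newdata) {
  if (inherits(model, "gp_model")) {
    if (model$kind != "regression")
      stop_icu("contract_violation", "day-of-discharge prediction needs a regression model")
    return(predict(model, newdata)$day)
  }
  if (!inherits(model, "integrated_model") || model$task != "regression")
    stop_icu("contract_violation", "day-of-discharge prediction needs a regression model")
  predict(model, newdata)$day
}

#' @export
print.integrated_model <- function(x, ...) {
  cat(sprintf("<integrated_model> %s: %d category submodels (%s), %d-fold stacking\n",
              x$task, length(x$submodels),
              paste(x$categories, collapse = ", "),
              length(unique(x$fold_id))))
  invisible(x)
}
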