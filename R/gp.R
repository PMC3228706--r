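# Gaussian-process models with an ARD squared-exponential kernel.
# Regression is exact; classification uses the Laplace approximation with a
# logistic link. Hyperparameters maximize the (approximate) log marginal
# likelihood by multi-restart L-BFGS on log-scale parameters with analytic
# gradients (implemented in src/gp_core.cpp).

#' Kernel and optimizer configuration for GP fitting
#'
#' @param restarts number of seeded optimizer restarts (the first start is
#'   deterministic; later starts perturb the initial log hyperparameters).
#' @param maxit maximum L-BFGS iterations per restart.
#' @param tol relative convergence tolerance of the marginal-likelihood
#'   optimization.
#' @param seed seed for restart initialization.
#' @param jitter_init initial diagonal jitter as a fraction of the signal
#'   variance; escalated tenfold on Cholesky failure.
#' @param jitter_max maximal jitter fraction before a numerical failure is
#'   raised.
#' @param newton_maxit,newton_tol Newton-iteration controls of the Laplace
#'   mode search (classification only).
#' @return an object of class `kernel_config`.
#' @export
kernel_config <- function(restarts = 5L, maxit = 100L, tol = 1e-6, seed = 1L,
                          jitter_init = 1e-8, jitter_max = 1e-2,
                          newton_maxit = 50L, newton_tol = 1e-10) {
  if (restarts < 1 || maxit < 1 || tol <= 0 || jitter_init <= 0 ||
      jitter_max < jitter_init)
    stop_icu("invalid_config", "invalid kernel_config")
  structure(list(restarts = as.integer(restarts), maxit = as.integer(maxit),
                 tol = tol, seed = as.integer(seed),
                 jitter_init = jitter_init, jitter_max = jitter_max,
                 newton_maxit = as.integer(newton_maxit),
                 newton_tol = newton_tol),
            class = "kernel_config")
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigendecomposition of the
# Jacobi matrix; cached. Used to integrate the logistic link over the latent
# Gaussian.
gauss_hermite <- local({
  cache <- list()
  function(n = 32L) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    out <- list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
    cache[[key]] <<- out
    out
  }
})

# E[plogis(f)] under f ~ N(mu, var), vectorized over test points
logistic_gauss_integral <- function(mu, var, gh = gauss_hermite()) {
  z <- outer(sqrt(2 * pmax(var, 0)), gh$nodes) + mu
  as.vector(plogis(z) %*% gh$weights) / sqrt(pi)
}

# evaluate nlml(+grad) with jitter escalation; env carries classification
# warm-start state
eval_nlml <- function(theta, X, target, kind, config, warm) {
  jit <- config$jitter_init
  d <- ncol(X)
  sf2 <- exp(theta[d + 1])
  repeat {
    res <- if (kind == "regression")
      cpp_gp_reg_nlml(X, target, theta, jit * sf2)
    else
      cpp_gp_cls_nlml(X, target, theta, warm$f, config$newton_maxit,
                      config$newton_tol, jit * sf2, TRUE)
    if (isTRUE(res$ok)) break
    jit <- jit * 10
    if (jit > config$jitter_max)
      stop_icu("numerical_failure",
               "kernel matrix not positive definite after jitter escalation")
  }
  if (kind == "classification") warm$f <- as.numeric(res$f_hat)
  res
}

gp_optimize <- function(X, target, kind, config) {
  d <- ncol(X)
  n_theta <- d + if (kind == "regression") 2L else 1L
  v0 <- 1
  if (kind == "regression") {
    v0 <- if (length(target) > 1) var(target) else 1
    if (!is.finite(v0)) v0 <- 1
    v0 <- max(v0, 1e-6)
  }
  theta0 <- c(rep(0.5 * log(max(d, 1)), d), log(v0),
              if (kind == "regression") log(0.1 * v0))
  set.seed(config$seed)
  perturb <- cbind(0, matrix(rnorm(n_theta * (config$restarts - 1), 0, 0.5),
                             n_theta))
  lower <- c(rep(-5, d), -15, if (kind == "regression") -15)
  upper <- c(rep(8, d), 6, if (kind == "regression") 6)

  best <- NULL
  lml_path <- numeric(0)
  for (r in seq_len(config$restarts)) {
    warm <- new.env()
    warm$f <- numeric(0)
    start <- pmin(pmax(theta0 + perturb[, r], lower), upper)
    last <- new.env()  # memoize: optim calls fn and gr at the same point
    fn <- function(th) {
      res <- eval_nlml(th, X, target, kind, config, warm)
      last$theta <- th
      last$res <- res
      res$nlml
    }
    gr <- function(th) {
      if (!is.null(last$theta) && isTRUE(all.equal(th, last$theta)))
        return(as.numeric(last$res$grad))
      as.numeric(eval_nlml(th, X, target, kind, config, warm)$grad)
    }
    opt <- tryCatch(
      optim(start, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = config$maxit,
                           factr = config$tol / .Machine$double.eps)),
      icudischarge_numerical_failure = function(e) NULL,
      error = function(e) NULL)
    if (is.null(opt)) next
    cand <- list(theta = opt$par, nlml = opt$value, warm_f = warm$f)
    if (is.null(best) || cand$nlml < best$nlml) best <- cand
    lml_path <- c(lml_path, -(if (is.null(best)) cand$nlml else best$nlml))
  }
  if (is.null(best))
    stop_icu("numerical_failure", "all optimizer restarts failed")
  best$lml_restarts <- lml_path
  best
}

#' Fit an exact Gaussian-process regression
#'
#' Squared-exponential kernel with one length-scale per feature (automatic
#' relevance determination), Gaussian observation noise, hyperparameters by
#' maximization of the exact log marginal likelihood. With
#' `transform = "log_day"` (the default for discharge-day modeling) the target
#' is modeled as `log(y - 0.5)`, which respects the discrete support on days
#' `>= 2` and the right skew of ICU length of stay; predictions are mapped
#' back and rounded.
#'
#' @param X numeric matrix of standardized features (no missing values).
#' @param y numeric target; outcome days (`>= 2`) under `"log_day"`.
#' @param config a [kernel_config()].
#' @param transform `"log_day"` or `"identity"`.
#' @return an object of class `gp_model` (kind `"regression"`).
#' @export
fit_gp_regression <- function(X, y, config = kernel_config(),
                              transform = c("log_day", "identity")) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y) || nrow(X) != length(y))
    stop_icu("contract_violation", "X and y must be complete and conformable")
  z <- if (transform == "log_day") {
    if (any(y < 2)) stop_icu("contract_violation",
                             "outcome days must be >= 2 under the log_day transform")
    log(y - 0.5)
  } else as.numeric(y)
  z_mean <- mean(z)            # the GP models the centered target
  z <- z - z_mean
  best <- gp_optimize(X, z, "regression", config)
  model <- structure(list(kind = "regression", X = X, y = as.numeric(y), z = z,
                          z_mean = z_mean,
                          transform = transform, theta = best$theta,
                          lml = -best$nlml, lml_restarts = best$lml_restarts,
                          config = config),
                     class = "gp_model")
  model$state <- gp_state(model)
  model
}

#' Fit a Laplace-approximate Gaussian-process classifier
#'
#' Binary classification with a logistic link. Newton iterations find the
#' posterior mode; the Laplace approximate log marginal likelihood drives
#' hyperparameter optimization; predictive class probabilities integrate the
#' logistic link over the latent Gaussian by Gauss-Hermite quadrature.
#'
#' @param X numeric matrix of standardized features (no missing values).
#' @param labels binary vector (0/1 or logical); both classes must be present.
#' @param config a [kernel_config()].
#' @return an object of class `gp_model` (kind `"classification"`).
#' @export
fit_gp_classification <- function(X, labels, config = kernel_config()) {
  X <- as.matrix(X)
  t01 <- as.numeric(labels)
  if (anyNA(X) || anyNA(t01) || nrow(X) != length(t01))
    stop_icu("contract_violation", "X and labels must be complete and conformable")
  if (!all(t01 %in% c(0, 1)) || length(unique(t01)) < 2)
    stop_icu("degenerate_labels", "labels must contain both classes")
  best <- gp_optimize(X, t01, "classification", config)
  model <- structure(list(kind = "classification", X = X, y = t01,
                          theta = best$theta, lml = -best$nlml,
                          lml_restarts = best$lml_restarts, config = config),
                     class = "gp_model")
  model$state <- gp_state(model)
  model
}

# cached decompositions for prediction, recomputed deterministically
gp_state <- function(model) {
  X <- model$X
  d <- ncol(X)
  theta <- model$theta
  sf2 <- exp(theta[d + 1])
  K <- cpp_kernel_se_ard(X, X, theta[seq_len(d)], theta[d + 1])
  jit_frac <- model$config$jitter_init
  repeat {
    jit <- jit_frac * sf2
    st <- if (model$kind == "regression") {
      sn2 <- exp(theta[d + 2])
      L <- tryCatch(t(chol(K + diag(sn2 + jit, nrow(X)))),
                    error = function(e) NULL)
      if (is.null(L)) NULL else
        list(L = L, alpha = backsolve(t(L), forwardsolve(L, model$z)),
             sn2 = sn2, sf2 = sf2)
    } else {
      fit <- cpp_gp_cls_nlml(X, model$y, theta, numeric(0),
                             model$config$newton_maxit,
                             model$config$newton_tol, jit, FALSE)
      if (!isTRUE(fit$ok)) NULL else {
        f_hat <- as.numeric(fit$f_hat)
        p <- plogis(f_hat)
        sW <- sqrt(p * (1 - p))
        B <- diag(nrow(X)) + (sW %o% sW) * (K + diag(jit, nrow(X)))
        L <- tryCatch(t(chol(B)), error = function(e) NULL)
        if (is.null(L)) NULL else
          list(L = L, f_hat = f_hat, grad_ll = model$y - p, sW = sW,
               sf2 = sf2)
      }
    }
    if (!is.null(st)) return(st)
    jit_frac <- jit_frac * 10
    if (jit_frac > model$config$jitter_max)
      stop_icu("numerical_failure",
               "kernel decomposition failed after jitter escalation")
  }
}

#' Predict from a fitted GP model
#'
#' @param object a `gp_model`.
#' @param newdata numeric feature matrix with the columns used at fit time.
#' @param ... unused.
#' @return a data frame with latent `mean` and `var` per test point; for
#'   classification additionally `prob` (second-day discharge probability);
#'   for regression additionally `day_cont` (continuous day scale) and `day`
#'   (integer day, `>= 2`).
#' @export
predict.gp_model <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  d <- ncol(object$X)
  theta <- object$theta
  ks <- cpp_kernel_se_ard(object$X, Xs, theta[seq_len(d)], theta[d + 1])
  st <- object$state
  if (object$kind == "regression") {
    mu <- object$z_mean + drop(crossprod(ks, st$alpha))
    v <- forwardsolve(st$L, ks)
    var <- pmax(st$sf2 - colSums(v^2), 0)
    if (object$transform == "log_day") {
      day_cont <- exp(mu) + 0.5
      data.frame(mean = mu, var = var, day_cont = day_cont,
                 day = pmax(2L, as.integer(floor(day_cont + 0.5))))
    } else data.frame(mean = mu, var = var)
  } else {
    mu <- drop(crossprod(ks, st$grad_ll))
    v <- forwardsolve(st$L, st$sW * ks)
    var <- pmax(st$sf2 - colSums(v^2), 0)
    data.frame(mean = mu, var = var,
               prob = logistic_gauss_integral(mu, var))
  }
}

#' ARD relevance ranking of the features
#'
#' Relevance of a feature is the inverse of its fitted kernel length-scale on
#' standardized inputs; larger means the latent function varies faster along
#' that feature. Ties keep column order.
#'
#' @param model a fitted `gp_model`.
#' @return data frame with `feature`, `relevance`, `rank`, sorted by
#'   decreasing relevance.
#' @export
relevance_ranking <- function(model) {
  if (!inherits(model, "gp_model"))
    stop_icu("unsupported_operation", "relevance_ranking needs a gp_model")
  d <- ncol(model$X)
  rel <- exp(-model$theta[seq_len(d)])
  feat <- colnames(model$X)
  if (is.null(feat)) feat <- paste0("x", seq_len(d))
  ord <- order(-rel)
  data.frame(feature = feat[ord], relevance = rel[ord],
             rank = seq_len(d), stringsAsFactors = FALSE)
}

#' @export
print.gp_model <- function(x, ...) {
  d <- ncol(x$X)
  cat(sprintf("<gp_model> %s, n = %d, d = %d, log marginal likelihood = %.3f\n",
              x$kind, nrow(x$X), d, x$lml))
  invisible(x)
}

#' Save / load a fitted GP model as text files
#'
#' Hyperparameters and metadata go to JSON; training arrays go to CSV with
#' full double precision (`%.17g`), so a reloaded model reproduces predictions
#' bit-identically on the same platform.
#'
#' @param model a `gp_model`.
#' @param dir directory to write to (created if needed).
#' @return `dir` (save) or the reloaded `gp_model` (load).
#' @export
save_gp_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(kind = model$kind, theta = sprintf("%.17g", model$theta),
               transform = model$transform, lml = sprintf("%.17g", model$lml),
               lml_restarts = sprintf("%.17g", model$lml_restarts),
               config = unclass(model$config),
               colnames = colnames(model$X))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  write_mat <- function(m, file)
    write.table(matrix(sprintf("%.17g", m), nrow(m)), file.path(dir, file),
                row.names = FALSE, col.names = FALSE, sep = ",", quote = FALSE)
  write_mat(model$X, "X.csv")
  write_mat(matrix(model$y, ncol = 1), "y.csv")
  invisible(dir)
}

#' @rdname save_gp_model
#' @param dir directory written by [save_gp_model()].
#' @export
load_gp_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  X <- as.matrix(read.csv(file.path(dir, "X.csv"), header = FALSE))
  dimnames(X) <- list(NULL, unlist(meta$colnames))
  y <- as.numeric(read.csv(file.path(dir, "y.csv"), header = FALSE)[[1]])
  cfg <- meta$config
  config <- kernel_config(cfg$restarts, cfg$maxit, cfg$tol, cfg$seed,
                          cfg$jitter_init, cfg$jitter_max, cfg$newton_maxit,
                          cfg$newton_tol)
  model <- structure(list(kind = meta$kind, X = X, y = y,
                          theta = as.numeric(unlist(meta$theta)),
                          lml = as.numeric(meta$lml),
                          lml_restarts = as.numeric(unlist(meta$lml_restarts)),
                          config = config),
                     class = "gp_model")
  if (meta$kind == "regression") {
    model$transform <- meta$transform
    z <- if (meta$transform == "log_day") log(y - 0.5) else y
    model$z_mean <- mean(z)
    model$z <- z - model$z_mean
  }
  model$state <- gp_state(model)
  model
}
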