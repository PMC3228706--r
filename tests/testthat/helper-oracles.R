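# Independent oracles: deliberately naive implementations used only to check
# the package's fast paths.

# Pincus ApEn by the definition, O(N^2) loops
apen_oracle <- function(x, m, r) {
  N <- length(x)
  phi <- function(k) {
    M <- N - k + 1
    lc <- numeric(M)
    for (i in seq_len(M)) {
      cnt <- 0
      for (j in seq_len(M)) {
        if (max(abs(x[i:(i + k - 1)] - x[j:(j + k - 1)])) <= r) cnt <- cnt + 1
      }
      lc[i] <- log(cnt / M)
    }
    mean(lc)
  }
  phi(m) - phi(m + 1)
}

# exact GP regression posterior by direct matrix inversion
gp_reg_oracle <- function(X, z, theta, Xtest, jitter_frac = 1e-8) {
  d <- ncol(X)
  sf2 <- exp(theta[d + 1])
  sn2 <- exp(theta[d + 2])
  K <- icudischarge:::cpp_kernel_se_ard(X, X, theta[seq_len(d)], theta[d + 1])
  ks <- icudischarge:::cpp_kernel_se_ard(X, Xtest, theta[seq_len(d)],
                                         theta[d + 1])
  Ky <- K + diag(sn2 + jitter_frac * sf2, nrow(X))
  Kinv <- solve(Ky)
  list(mean = drop(t(ks) %*% Kinv %*% z),
       var = sf2 - diag(t(ks) %*% Kinv %*% ks))
}

# GP classification predictive probabilities by integration over the latent
# posterior: importance sampling from the exact latent prior with per-sample
# Gauss-Hermite integration of the conditional link expectation
gp_cls_oracle <- function(X, y, theta, Xtest, S = 2e5, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  d <- ncol(X)
  sf2 <- exp(theta[d + 1])
  K <- icudischarge:::cpp_kernel_se_ard(X, X, theta[seq_len(d)], theta[d + 1]) +
    diag(1e-8 * sf2, n)
  L <- t(chol(K))
  F <- L %*% matrix(rnorm(n * S), n, S)
  lik <- exp(colSums(log(plogis((2 * y - 1) * F))))
  ks <- icudischarge:::cpp_kernel_se_ard(X, Xtest, theta[seq_len(d)],
                                         theta[d + 1])
  A <- solve(K, ks)
  mu_cond <- t(F) %*% A
  v_cond <- sf2 * (1 + 1e-8) - colSums(ks * A)
  gh <- icudischarge:::gauss_hermite(16)
  vapply(seq_len(ncol(ks)), function(j) {
    zz <- outer(mu_cond[, j], sqrt(2 * max(v_cond[j], 0)) * gh$nodes, "+")
    ev <- as.vector(plogis(zz) %*% gh$weights) / sqrt(pi)
    sum(ev * lik) / sum(lik)
  }, numeric(1))
}

# aROC as the proportion of concordant positive/negative pairs (+ half ties)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# classifier object at fixed hyperparameters (bypasses fitting, so the
# inference approximation can be checked at a prescribed prior)
mk_cls_model <- function(X, y, theta) {
  m <- structure(list(kind = "classification", X = as.matrix(X),
                      y = as.numeric(y), theta = theta,
                      config = kernel_config()), class = "gp_model")
  m$state <- icudischarge:::gp_state(m)
  m
}

# regression counterpart: fixed hyperparameters, identity transform
mk_reg_model <- function(X, y, theta, center = TRUE) {
  z_mean <- if (center) mean(y) else 0
  m <- structure(list(kind = "regression", X = as.matrix(X),
                      y = as.numeric(y), z = as.numeric(y) - z_mean,
                      z_mean = z_mean, transform = "identity", theta = theta,
                      config = kernel_config()), class = "gp_model")
  m$state <- icudischarge:::gp_state(m)
  m
}

# small cached cohorts so multiple test files can reuse them
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(n = 120, seed = 3, label = "development", ...) {
  key <- paste(n, seed, label, ...)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(
      generator_config(n, seed = seed, label = label, ...))
  .fixture_env[[key]]
}
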