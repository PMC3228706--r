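test_that("fitted GP regression reproduces the closed-form posterior", {
  set.seed(20)
  for (rep in 1:8) {
    n <- sample(3:10, 1)
    d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    m <- fit_gp_regression(X, y, kernel_config(restarts = 2, maxit = 50),
                           transform = "identity")
    Xt <- matrix(rnorm(5 * d), 5, d)
    p <- predict(m, Xt)
    o <- gp_reg_oracle(X, y - mean(y), m$theta, Xt)
    expect_equal(p$mean, o$mean + mean(y), tolerance = 1e-8)
    expect_equal(p$var, pmax(o$var, 0), tolerance = 1e-8)
  }
})

test_that("noise-free limit interpolates and degenerate targets stay flat", {
  # single training point, vanishing noise: the posterior interpolates it
  m1 <- mk_reg_model(matrix(0), 1.7, theta = c(0, 0, log(1e-12)),
                     center = FALSE)
  p1 <- predict(m1, matrix(0))
  expect_lt(abs(p1$mean - 1.7), 1e-6)
  expect_lt(p1$var, 1e-6)
  # constant targets: constant predictive mean, near-zero signal variance
  X <- matrix(seq(-1, 1, length.out = 6))
  mc <- fit_gp_regression(X, rep(4, 6),
                          kernel_config(restarts = 1, maxit = 50),
                          transform = "log_day")
  pc <- predict(mc, matrix(c(-2, 0, 2)))
  expect_equal(pc$day, rep(4L, 3))
  expect_lt(exp(mc$theta[2]), 1e-4)
})

test_that("day mapping rounds the continuous prediction and clips at day 2", {
  X <- matrix(c(0, 1))
  m <- fit_gp_regression(X, c(2, 3), kernel_config(restarts = 1, maxit = 50))
  p <- predict(m, matrix(c(0, 0.5, 1)))
  expect_identical(p$day, pmax(2L, as.integer(floor(p$day_cont + 0.5))))
  expect_true(all(p$day >= 2L))
  m2 <- fit_gp_regression(matrix(c(0, 1)), c(2, 2),
                          kernel_config(restarts = 1, maxit = 50))
  expect_identical(predict(m2, matrix(c(-3, 5)))$day, c(2L, 2L))
})

test_that("Laplace classification agrees with the latent-space quadrature oracle", {
  worst <- 0
  for (s in 1:6) {
    set.seed(s)
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n), ncol = 1)
    y <- rbinom(n, 1, plogis(1.5 * X[, 1]))
    if (length(unique(y)) < 2) y[which.max(abs(X[, 1]))] <- 1 - y[which.max(abs(X[, 1]))]
    theta <- c(0, 0)  # unit length-scale and signal variance
    m <- mk_cls_model(X, y, theta)
    Xt <- matrix(seq(-2, 2, length.out = 7), ncol = 1)
    diff <- max(abs(predict(m, Xt)$prob -
                      gp_cls_oracle(X, y, theta, Xt, seed = s + 300)))
    worst <- max(worst, diff)
  }
  expect_lt(worst, 0.02)
})

test_that("classification degenerates to the symmetric prior far from data", {
  m <- fit_gp_classification(matrix(c(0, 0.3)), c(0, 1),
                             kernel_config(restarts = 1, maxit = 40))
  p_far <- predict(m, matrix(50))$prob
  expect_lt(abs(p_far - 0.5), 1e-3)
  expect_error(fit_gp_classification(matrix(rnorm(5)), rep(1, 5)),
               class = "icudischarge_degenerate_labels")
})

test_that("separable 2-D toy data reaches training aROC 1", {
  set.seed(33)
  X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c(0, 1), each = 10)
  m <- fit_gp_classification(X, y, kernel_config(restarts = 2, maxit = 60))
  expect_equal(auc(predict(m, X)$prob, y), 1)
})

test_that("optimizer bookkeeping and variance bounds hold", {
  set.seed(40)
  X <- matrix(rnorm(30), 15, 2)
  y <- X[, 1] + rnorm(15, 0, 0.3)
  m <- fit_gp_regression(X, y, kernel_config(restarts = 4, maxit = 40),
                         transform = "identity")
  expect_true(all(diff(m$lml_restarts) >= -1e-10))  # best-so-far is monotone
  p <- predict(m, matrix(rnorm(40), 20, 2))
  expect_true(all(p$var >= 0))
  expect_true(all(p$var <= exp(m$theta[3]) + exp(m$theta[4]) + 1e-8))
})

test_that("ARD ranks a planted feature first in nearly every seeded run", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 80
    X <- matrix(rnorm(n * 11), n, 11,
                dimnames = list(NULL, paste0("f", 1:11)))
    y <- 1.5 * X[, 4] + rnorm(n, 0, 0.4)
    m <- fit_gp_regression(X, y, kernel_config(restarts = 1, maxit = 40),
                           transform = "identity")
    if (relevance_ranking(m)$feature[1] == "f4") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("a duplicated informative feature keeps both copies highly ranked", {
  top2 <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 80
    X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    X[, 8] <- X[, 1]
    y <- 1.5 * X[, 1] + rnorm(n, 0, 0.4)
    m <- fit_gp_regression(X, y, kernel_config(restarts = 1, maxit = 40),
                           transform = "identity")
    rk <- relevance_ranking(m)
    if (all(c("f1", "f8") %in% rk$feature[1:3])) top2 <- top2 + 1
  }
  expect_gte(top2, 4)
})

test_that("a saved model reloads to bit-identical predictions", {
  set.seed(50)
  X <- matrix(rnorm(40), 20, 2)
  y <- as.numeric(X[, 1] + rnorm(20, 0, 0.5) > 0)
  m <- fit_gp_classification(X, y, kernel_config(restarts = 1, maxit = 40))
  d <- file.path(tempdir(), "gpmod")
  save_gp_model(m, d)
  m2 <- load_gp_model(d)
  Xt <- matrix(rnorm(20), 10, 2)
  expect_identical(predict(m, Xt), predict(m2, Xt))
  mr <- fit_gp_regression(X, X[, 1] + rnorm(20, 0, 0.2),
                          kernel_config(restarts = 1, maxit = 40),
                          transform = "identity")
  dr <- file.path(tempdir(), "gpmodr")
  save_gp_model(mr, dr)
  expect_identical(predict(mr, Xt), predict(load_gp_model(dr), Xt))
  unlink(c(d, dr), recursive = TRUE)
})

test_that("stacking is faithful under redundancy and guards its inputs", {
  set.seed(60)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4)
  y <- as.numeric(plogis(X[, 1] + 0.5 * X[, 2] + rnorm(n)) > 0.5)
  kc <- kernel_config(restarts = 1, maxit = 40)
  f5 <- lapply(setNames(1:5, paste0("c", 1:5)), function(i) X)
  m5 <- fit_integrated_model(f5, y, "classification", kc, folds = 3, seed = 9)
  m1 <- fit_integrated_model(list(c1 = X), y, "classification", kc,
                             folds = 3, seed = 9)
  Xt <- matrix(rnorm(30 * 4), 30, 4)
  p5 <- predict(m5, lapply(f5, function(z) Xt))$prob
  p1 <- predict(m1, list(c1 = Xt))$prob
  expect_lt(max(abs(p5 - p1)), 1e-3)
  expect_error(fit_integrated_model(list(a = X), y, "classification",
                                    categories = c("a", "b")),
               class = "icudischarge_invalid_config")
  expect_error(predict(m1, list(zzz = Xt)),
               class = "icudischarge_invalid_config")
})

test_that("integration does not lose an informative category to noise ones", {
  mk <- function(n) {
    list(informative = matrix(rnorm(n * 3), n, 3),
         n1 = matrix(rnorm(n * 3), n, 3), n2 = matrix(rnorm(n * 3), n, 3),
         n3 = matrix(rnorm(n * 3), n, 3), n4 = matrix(rnorm(n * 3), n, 3))
  }
  kc <- kernel_config(restarts = 1, maxit = 30)
  gap <- vapply(1:4, function(s) {
    set.seed(70 + s)
    n <- 150
    fd <- mk(n)
    fv <- mk(n)
    yd <- as.numeric(plogis(1.5 * fd$informative[, 1] + rnorm(n, 0, 0.7)) > 0.5)
    yv <- as.numeric(plogis(1.5 * fv$informative[, 1] + rnorm(n, 0, 0.7)) > 0.5)
    int <- fit_integrated_model(fd, yd, "classification", kc, folds = 5,
                                seed = s)
    sub <- fit_gp_classification(fd$informative, yd, kc)
    auc(predict(int, fv)$prob, yv) - auc(predict(sub, fv$informative)$prob, yv)
  }, numeric(1))
  expect_gte(mean(gap), -0.02)
})
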