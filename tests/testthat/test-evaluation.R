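test_that("auc handles separation, ties and the concordance definition", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc(c(0.2, 0.8, 0.4, 0.9), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:4, c(1, 1, 1, 1)), class = "icudischarge_undefined_metric")
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2))  # coarse grid forces ties
    expect_identical(auc(s, y), auc_oracle(s, y))
  }
})

test_that("auc and the DeLong test agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  y <- rbinom(120, 1, 0.35)
  a <- rnorm(120) + y
  b <- rnorm(120) + 0.5 * y
  expect_equal(auc(a, y), as.numeric(pROC::auc(pROC::roc(y, a, quiet = TRUE))))
  dl <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong",
                        paired = TRUE)
  expect_equal(dl$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("DeLong internal aROC matches auc() and rank-shifts are degenerate", {
  set.seed(3)
  y <- rbinom(80, 1, 0.4)
  a <- rnorm(80) + y
  b <- rnorm(80)
  dl <- delong_test(a, b, y)
  expect_equal(dl$estimate, auc(a, y) - auc(b, y), tolerance = 1e-12)
  expect_error(delong_test(a, a + 5, y),
               class = "icudischarge_degenerate_comparison")
})

test_that("Brier score and its scaled version behave at the reference points", {
  y <- c(0, 1, 1, 0)
  expect_equal(brier(y, y), 0)
  expect_equal(brier(rep(0.5, 4), y), 0.25)
  s <- 0.3
  set.seed(4)
  yy <- rbinom(500, 1, s)
  expect_equal(brier_scaled(brier(rep(mean(yy), 500), yy), mean(yy)), 0)
  expect_error(brier_scaled(0.1, 1), class = "icudischarge_undefined_metric")
})

test_that("the Brier decomposition identity is exact for bin-constant forecasts", {
  set.seed(5)
  p <- sample(c(0.25, 0.85), 200, replace = TRUE)
  y <- rbinom(200, 1, p)
  dec <- brier_decomposition(p, y, n_bins = 10)
  expect_lt(abs(dec$remainder), 1e-12)
  expect_equal(dec$brier,
               dec$reliability - dec$resolution + dec$uncertainty,
               tolerance = 1e-12)
  # constant forecast at prevalence: BS = uncertainty
  s <- mean(y)
  dec2 <- brier_decomposition(rep(s, 200), y)
  expect_equal(dec2$reliability, 0, tolerance = 1e-12)
  expect_equal(dec2$resolution, 0, tolerance = 1e-12)
  expect_equal(dec2$brier, dec2$uncertainty, tolerance = 1e-12)
  # uncertainty is s(1-s)
  expect_equal(brier_decomposition(runif(100), rep(c(1, 0), c(30, 70)))$uncertainty,
               0.21)
})

test_that("Hosmer-Lemeshow is zero for perfectly grouped forecasts and detects miscalibration", {
  p <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  y <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(pr)
    rep(c(1, 0), round(c(pr, 1 - pr) * 20))))
  hl <- hosmer_lemeshow(p, y)
  expect_lt(hl$statistic, 1e-10)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, 8)
  # severe miscalibration: forecasts p, outcomes from p^2
  set.seed(6)
  pp <- runif(499, 0.05, 0.95)
  yy <- rbinom(499, 1, pp^2)
  expect_lt(hosmer_lemeshow(pp, yy)$p_value, 0.001)
  expect_error(hosmer_lemeshow(rep(0.5, 50), rbinom(50, 1, 0.5)),
               class = "icudischarge_undefined_metric")
})

test_that("bootstrap Brier comparison is exact in the degenerate cases", {
  set.seed(7)
  y <- rbinom(100, 1, 0.4)
  p <- runif(100)
  same <- bootstrap_brier_diff(p, p, y, B = 200, seed = 1)
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)
  # extreme separation: perfect vs uninformative forecasts
  y2 <- rbinom(499, 1, 0.3)
  sep <- bootstrap_brier_diff(as.numeric(y2), rep(0.5, 499), y2,
                              B = 3000, seed = 2)
  expect_lt(sep$p_value, 0.001)
  expect_error(bootstrap_brier_diff(p, p, y, B = 1),
               class = "icudischarge_invalid_config")
  expect_warning(bootstrap_brier_diff(p, p, y, B = 50, seed = 1),
                 class = "icudischarge_small_B")
})

test_that("LPF and RMSRE follow their definitions", {
  expect_equal(lpf(4, 3), 0.25)
  expect_equal(lpf(2, 3), -0.5)
  expect_equal(lpf_summary(c(3, 4, 5), c(3, 4, 5)),
               list(median = 0, p25 = 0, p75 = 0, n_zero = 3L,
                    pct_zero = 100))
  expect_equal(rmsre(c(2, 4), c(2, 2)), sqrt((0 + 0.25) / 2), tolerance = 1e-12)
  expect_equal(rmsre(c(2, 4), c(2, 2)), 0.35355, tolerance = 1e-4)
  expect_equal(rmsre(c(3, 5, 7), c(3, 5, 7)), 0)
  set.seed(8)
  a <- sample(2:9, 30, replace = TRUE)
  p <- sample(2:9, 30, replace = TRUE)
  expect_equal(rmsre(a, p)^2, mean(lpf(a, p)^2), tolerance = 1e-12)
  expect_error(lpf(1, 2), class = "icudischarge_contract_violation")
})

test_that("Mann-Whitney comparison matches exact small-sample behavior", {
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p_value, 1)
  mw <- mann_whitney(c(1, 2, 3), c(101, 102, 103))
  expect_equal(unname(mw$statistic), 0)  # U = 0: complete separation
  big <- mann_whitney(1:30, 101:130)
  expect_lt(big$p_value, 0.05)
  set.seed(9)
  a <- rnorm(20)
  b <- rnorm(25, 0.5)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
})

test_that("the 2x2 chi-square reproduces known cohort-comparison p-values", {
  # repeat cardiac surgery: 27/462 vs 49/499
  rs <- chi_square_2x2(27, 462 - 27, 49, 499 - 49)
  expect_equal(round(rs$p_value, 3), 0.023)
  # hospital mortality: 15/462 vs 16/499
  hm <- chi_square_2x2(15, 462 - 15, 16, 499 - 16)
  expect_equal(round(hm$p_value, 2), 0.97)
  prop <- chi_square_2x2(10, 90, 20, 180)
  expect_equal(unname(prop$statistic), 0, tolerance = 1e-12)
  expect_equal(prop$p_value, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5),
               class = "icudischarge_undefined_metric")
})

test_that("the prevalence table pools late days and ties out with LPF", {
  a <- c(2, 2, 3, 4, 15, 20)
  p <- c(2, 3, 3, 4, 16, 3)
  tab <- prevalence_table(a, p)
  expect_equal(sum(tab$n_actual), length(a))
  expect_equal(sum(tab$n_true_positive), sum(lpf(a, p) == 0))
  perfect <- prevalence_table(a, a)
  expect_equal(perfect$n_predicted, perfect$n_actual)
  expect_equal(perfect$n_true_positive, perfect$n_actual)
})

test_that("metrics are invariant to patient reordering", {
  set.seed(10)
  y <- rbinom(150, 1, 0.3)
  p <- plogis(rnorm(150) + y)
  perm <- sample(150)
  expect_equal(auc(p, y), auc(p[perm], y[perm]))
  expect_equal(brier(p, y), brier(p[perm], y[perm]))
  expect_equal(hosmer_lemeshow(p, y)$statistic,
               hosmer_lemeshow(p[perm], y[perm])$statistic)
  q <- plogis(rnorm(150))
  expect_equal(delong_test(p, q, y)$p_value,
               delong_test(p[perm], q[perm], y[perm])$p_value)
})

test_that("the Youden cutoff separates a separable sample", {
  cut <- roc_best_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cut$youden, 1)
  expect_gt(cut$cutoff, 0.2)
  expect_lte(cut$cutoff, 0.8)
})
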