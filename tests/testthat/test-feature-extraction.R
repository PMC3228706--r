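test_that("imputation statistics use observed values and healthy levels", {
  dev <- small_cohort(120, seed = 3)
  stats <- fit_imputation_stats(dev)
  expect_identical(stats$fitted_on, "development")
  # mean over observed values only
  hr <- dev$admission$preop_hr
  expect_equal(unname(stats$numeric_means["preop_hr"]),
               mean(hr, na.rm = TRUE))
  # a fully missing categorical collapses to its healthy level
  co <- small_cohort(40, seed = 9)
  co$admission$rhythm <- NA_character_
  fm <- build_feature_matrix(co, "admission", stats)
  afib_raw <- fm$values[, "rhythm_afib"] * fm$standardization$sd["rhythm_afib"] +
    fm$standardization$mean["rhythm_afib"]
  expect_true(all(abs(afib_raw) < 1e-12))
})

test_that("laboratory value/count/trend follow the one-SD rule", {
  f <- lab_features(c(5.0, 7.0, 7.2), sd = 1.0)
  expect_equal(f, list(value = 7.2, count = 3, trend = 1))
  expect_equal(lab_features(c(5.0, 5.4), sd = 1.0)$trend, 0)
  expect_equal(lab_features(c(5.0, 3.2), sd = 1.0)$trend, -1)
  single <- lab_features(5.0, sd = 1.0)
  expect_equal(single$count, 1)
  expect_equal(single$trend, 0)
  expect_error(lab_features(numeric(0), sd = 1),
               class = "icudischarge_missing_analyte")
})

test_that("peak shaving removes only >2 SD deviations from the series mean", {
  x <- c(rep(0, 9), 100, rep(NA, 230))
  # mean 10, population SD 30: |100 - 10| = 90 > 60 removed, zeros kept
  shaved <- peak_shave(x)
  expect_true(is.na(shaved[10]))
  expect_equal(shaved[1:9], rep(0, 9))
  # constant series: SD 0, nothing removed
  expect_equal(peak_shave(rep(5, 240)), rep(5, 240))
  # series within 2 SD everywhere: identity (uniform noise never exceeds
  # sqrt(3) ~ 1.73 population SDs)
  set.seed(1)
  y <- runif(240)
  expect_equal(peak_shave(y), y)
  expect_error(peak_shave(c(1, rep(NA, 239))),
               class = "icudischarge_unusable_series")
})

test_that("interpolation fills interior gaps linearly and carries boundaries", {
  expect_equal(interpolate_gaps(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_gaps(c(NA, 2, 4)), c(2, 2, 4))
  expect_equal(interpolate_gaps(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(interpolate_gaps(c(NA, NA, 7, NA)), c(7, 7, 7, 7))
  expect_error(interpolate_gaps(rep(NA_real_, 10)),
               class = "icudischarge_unusable_series")
})

test_that("window statistics partition the series into six 40-minute blocks", {
  idx <- window_stats(0:239)
  expect_equal(idx$mean, c(19.5, 59.5, 99.5, 139.5, 179.5, 219.5))
  const <- window_stats(rep(3.7, 240))
  expect_equal(const$mean, rep(3.7, 6))
  expect_equal(const$var, rep(0, 6))
  pw <- window_stats(rep(1:6, each = 40))
  expect_equal(pw$mean, as.numeric(1:6))
  expect_equal(pw$var, rep(0, 6))
  expect_error(window_stats(1:100), class = "icudischarge_contract_violation")
})

test_that("shave-then-interpolate is idempotent and window stats rotate with the series", {
  # bounded baseline noise plus large spike artifacts and gaps: the spikes
  # are removed on the first pass and nothing further can exceed the bound
  set.seed(4)
  x <- runif(240)
  x[sample(240, 30)] <- NA
  x[sample(which(!is.na(x)), 3)] <- 25
  once <- interpolate_gaps(peak_shave(x))
  twice <- interpolate_gaps(peak_shave(once))
  expect_equal(twice, once)
  # shifting by one window rotates the window features
  y <- rnorm(240)
  shifted <- c(y[41:240], y[1:40])
  expect_equal(window_stats(shifted)$mean,
               window_stats(y)$mean[c(2:6, 1)])
  expect_equal(window_stats(shifted)$var,
               window_stats(y)$var[c(2:6, 1)])
})

test_that("approximate entropy matches the brute-force definition to 1e-10", {
  p <- apen_params(m = 2, r = 0.2)
  expect_equal(approx_entropy(rep(2, 50), p), 0)
  set.seed(11)
  for (len in c(40, 120, 300)) {
    x <- rnorm(len)
    r_abs <- p$r * icudischarge:::pop_sd(x)
    expect_equal(approx_entropy(x, p), apen_oracle(x, 2, r_abs),
                 tolerance = 1e-10)
  }
  # strictly alternating two-level series, m = 2
  alt <- rep(c(0, 1), 30)
  expect_equal(approx_entropy(alt, p),
               apen_oracle(alt, 2, 0.2 * icudischarge:::pop_sd(alt)),
               tolerance = 1e-10)
  # white noise is less regular than the same-variance alternating series
  set.seed(12)
  for (s in 1:5) {
    w <- sample(c(0, 1), 60, replace = TRUE)
    if (icudischarge:::pop_sd(w) == 0) next
    expect_gt(approx_entropy(w, p), approx_entropy(alt[1:60], p))
  }
})

test_that("the dynamic category has exactly 63 columns with provenance", {
  dev <- small_cohort(120, seed = 3)
  stats <- fit_imputation_stats(dev)
  fm <- build_feature_matrix(dev, "dynamic", stats)
  expect_equal(ncol(fm$values), 6 * 2 * 5 + 3)
  expect_equal(sum(fm$descriptors$statistic == "apen"), 3)
  expect_equal(sum(fm$descriptors$statistic == "mean"), 30)
  expect_equal(sum(fm$descriptors$statistic == "variance"), 30)
  expect_equal(sort(unique(fm$descriptors$window[!is.na(fm$descriptors$window)])),
               1:6)
  expect_false(anyNA(fm$values))
})

test_that("with no missingness the imputation constants are never used", {
  co <- generate_cohort(generator_config(50, seed = 17, missing_rate = 0,
                                         label = "development"))
  stats <- fit_imputation_stats(co)
  poked <- stats
  for (cat in names(poked$feature_means))
    poked$feature_means[[cat]][] <- 1e6  # would wreck any imputed cell
  for (cat in c("laboratory", "physiological", "dynamic")) {
    a <- build_feature_matrix(co, cat, stats)
    b <- build_feature_matrix(co, cat, poked)
    expect_equal(a$values, b$values)
  }
})

test_that("validation features reuse development statistics without refitting", {
  dev <- small_cohort(120, seed = 3)
  val <- small_cohort(90, seed = 44, label = "validation")
  stats <- fit_imputation_stats(dev)
  fd <- build_feature_matrices(dev, stats)
  fv <- build_feature_matrices(val, stats)
  for (cat in names(fd)) {
    expect_identical(fv[[cat]]$fitted_on, "development")
    expect_identical(fv[[cat]]$standardization, fd[[cat]]$standardization)
    # development columns are centered and unit-scale; validation need not be
    expect_lt(max(abs(colMeans(fd[[cat]]$values))), 1e-10)
    sds <- apply(fd[[cat]]$values, 2, icudischarge:::pop_sd)
    expect_true(all(abs(sds[sds > 0] - 1) < 1e-10))
  }
  expect_gt(max(abs(colMeans(fv$admission$values))), 1e-6)
})

test_that("unknown categories and bad apen parameters are rejected", {
  dev <- small_cohort(40, seed = 9)
  stats <- fit_imputation_stats(dev)
  expect_error(build_feature_matrix(dev, "genomics", stats),
               class = "icudischarge_contract_violation")
  expect_error(apen_params(m = 0), class = "icudischarge_invalid_config")
  expect_error(apen_params(r = -1), class = "icudischarge_invalid_config")
})
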