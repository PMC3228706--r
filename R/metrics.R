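# Evaluation suite for the two prediction tasks: discrimination and
# calibration of the second-day-discharge probabilities, and relative-error
# summaries of the discrete day-of-discharge predictions, plus the paired
# statistical comparisons between models.

check_binary <- function(labels) {
  y <- as.numeric(labels)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_icu("contract_violation", "labels must be binary 0/1")
  if (length(unique(y)) < 2)
    stop_icu("undefined_metric", "both outcome classes must be present")
  y
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with half credit for tied scores; equals the
#' trapezoidal area under the empirical ROC curve, and the probability that a
#' random positive outranks a random negative.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary outcomes.
#' @return aROC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- check_binary(labels)
  if (length(scores) != length(y) || anyNA(scores))
    stop_icu("contract_violation", "scores must be complete and match labels")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each positive, the mean placement against
# all negatives (and vice versa), computed with midranks.
delong_components <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong test comparing two correlated aROCs
#'
#' Paired comparison of the aROCs of two score vectors on the same patients,
#' using the DeLong structural-components estimate of the covariance of the
#' two areas and a two-sided normal test on their difference.
#'
#' @param scores_a,scores_b paired numeric predictions.
#' @param labels binary outcomes.
#' @return a `comparison_result` with the aROC difference and p-value.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- check_binary(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop_icu("contract_violation", "paired scores must match labels")
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- var(cbind(ca$v10, cb$v10))
  s01 <- var(cbind(ca$v01, cb$v01))
  S <- s10 / ca$m + s01 / ca$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(v) || v <= 0)
    stop_icu("degenerate_comparison",
             "zero variance of the aROC difference (identical rankings?)")
  z <- (ca$auc - cb$auc) / sqrt(v)
  comparison_result("aROC", statistic = z,
                    p_value = 2 * pnorm(-abs(z)), method = "DeLong",
                    estimate = ca$auc - cb$auc)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' 0 is perfect, 0.25 is the conventional upper cut-off for acceptability.
#'
#' @param probabilities forecasts in `[0, 1]`.
#' @param labels binary outcomes.
#' @return Brier score in `[0, 1]`.
#' @export
brier <- function(probabilities, labels) {
  y <- as.numeric(labels)
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1))
    stop_icu("contract_violation", "probabilities must lie in [0, 1]")
  mean((probabilities - y)^2)
}

#' Brier score scaled (skill versus climatology), as a percent
#'
#' `BSS = 1 - BS / (s (1 - s))` where `s` is the outcome prevalence, clipped
#' below at 0 and expressed as a percent; a forecast no better than always
#' predicting the prevalence scores 0%.
#'
#' @param bs a Brier score.
#' @param s outcome prevalence in `(0, 1)`.
#' @return percent in `[0, 100]`.
#' @export
brier_scaled <- function(bs, s) {
  if (s <= 0 || s >= 1)
    stop_icu("undefined_metric", "BSS undefined when only one class occurs")
  100 * max(0, 1 - bs / (s * (1 - s)))
}

#' Brier score decomposition: reliability - resolution + uncertainty
#'
#' Forecasts are grouped into equal-width probability bins; per bin k with
#' `n_k` forecasts, mean forecast `p_k` and observed positive fraction `o_k`:
#' reliability is the weighted mean of `(p_k - o_k)^2`, resolution the
#' weighted mean of `(o_k - s)^2`, uncertainty `s (1 - s)`. The identity
#' `BS = reliability - resolution + uncertainty` is exact when forecasts are
#' constant within each bin; otherwise the within-bin variance remainder is
#' reported.
#'
#' @param probabilities forecasts in `[0, 1]`.
#' @param labels binary outcomes.
#' @param n_bins number of equal-width bins on `[0, 1]`.
#' @return list with the three terms, the remainder, and the
#'   `reliability_table` (per-bin `n_k`, `p_k`, `o_k`).
#' @export
brier_decomposition <- function(probabilities, labels, n_bins = 10L) {
  y <- as.numeric(labels)
  if (n_bins < 1) stop_icu("invalid_config", "n_bins must be >= 1")
  bin <- pmin(floor(probabilities * n_bins) + 1L, n_bins)
  N <- length(y)
  s <- mean(y)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(k) {
    idx <- bin == k
    data.frame(bin = k, n_k = sum(idx), p_k = mean(probabilities[idx]),
               o_k = mean(y[idx]))
  }))
  reliability <- sum(tab$n_k * (tab$p_k - tab$o_k)^2) / N
  resolution <- sum(tab$n_k * (tab$o_k - s)^2) / N
  uncertainty <- s * (1 - s)
  bs <- brier(probabilities, y)
  list(reliability = reliability, resolution = resolution,
       uncertainty = uncertainty,
       remainder = bs - (reliability - resolution + uncertainty),
       brier = bs, s = s, n = N, reliability_table = tab)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into deciles of predicted risk (equal counts, tied
#' probabilities kept together), compares observed and expected events per
#' group with a chi-square statistic on `n_groups - 2` degrees of freedom. A
#' p-value above 0.05 is the conventional calibration-acceptability cut-off.
#'
#' @param probabilities forecasts in `[0, 1]`.
#' @param labels binary outcomes.
#' @param n_groups number of risk groups (default deciles).
#' @return list with `statistic`, `df`, `p_value` and the per-group table.
#' @export
hosmer_lemeshow <- function(probabilities, labels, n_groups = 10L) {
  y <- as.numeric(labels)
  if (n_groups < 2) stop_icu("invalid_config", "n_groups must be >= 2")
  br <- unique(quantile(probabilities, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(br) < 3)
    stop_icu("undefined_metric",
             "not enough distinct probabilities to form risk groups")
  grp <- cut(probabilities, breaks = br, include.lowest = TRUE)
  tab <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- grp == g
    data.frame(group = g, n = sum(idx), observed = sum(y[idx]),
               expected = sum(probabilities[idx]),
               mean_p = mean(probabilities[idx]))
  }))
  tab <- tab[tab$n > 0, ]  # tied quantile breaks can leave empty levels
  if (nrow(tab) < 3)
    stop_icu("undefined_metric",
             "not enough distinct probabilities to form risk groups")
  # a group whose expected count vanishes is merged into its neighbor
  while (nrow(tab) > 2 &&
         any(bad <- tab$n * tab$mean_p * (1 - tab$mean_p) < 1e-12)) {
    i <- which(bad)[1]
    j <- if (i == 1) 2 else i - 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$mean_p[j] <- tab$expected[j] / tab$n[j]
    tab <- tab[-i, ]
    warn_icu("merged_group", "risk group with zero expected count merged")
  }
  stat <- sum((tab$observed - tab$n * tab$mean_p)^2 /
                (tab$n * tab$mean_p * (1 - tab$mean_p)))
  df <- nrow(tab) - 2
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Paired bootstrap comparison of two Brier scores
#'
#' Resamples patients with replacement `B` times; the two-sided p-value is
#' twice the smaller tail fraction of the bootstrap distribution of the Brier
#' score difference around zero, with the `(B + 1)` small-sample correction.
#'
#' @param probabilities_a,probabilities_b paired forecasts.
#' @param labels binary outcomes.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return a `comparison_result` with the observed difference (a minus b).
#' @export
bootstrap_brier_diff <- function(probabilities_a, probabilities_b, labels,
                                 B = 1000L, seed = 1L) {
  y <- as.numeric(labels)
  n <- length(y)
  if (length(probabilities_a) != n || length(probabilities_b) != n)
    stop_icu("contract_violation", "paired forecasts must match labels")
  if (B < 2) stop_icu("invalid_config", "B must be at least 2")
  if (B < 100) warn_icu("small_B", "fewer than 100 bootstrap replicates")
  d_i <- (probabilities_a - y)^2 - (probabilities_b - y)^2
  obs <- mean(d_i)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  d_star <- colMeans(matrix(d_i[idx], n, B))
  p <- 2 * min((1 + sum(d_star <= 0)) / (B + 1),
               (1 + sum(d_star >= 0)) / (B + 1))
  comparison_result("Brier score", statistic = obs, p_value = min(1, p),
                    method = "bootstrap-Brier", estimate = obs)
}

#' Loss penalty function of day-of-discharge predictions
#'
#' `LPF = (actual - predicted) / actual`: 0 means the exact day was hit;
#' positive values mean the stay was under-predicted, and an error of the
#' same number of days is penalized less the later the actual discharge.
#'
#' @param actual_days,predicted_days integer days `>= 2`.
#' @return numeric vector of per-patient LPF values.
#' @export
lpf <- function(actual_days, predicted_days) {
  if (any(actual_days < 2) || any(predicted_days < 2) ||
      any(actual_days != round(actual_days)) ||
      any(predicted_days != round(predicted_days)))
    stop_icu("contract_violation", "days must be integers >= 2")
  (actual_days - predicted_days) / actual_days
}

#' Summary of the loss penalty function
#'
#' @inheritParams lpf
#' @return list with `median`, `p25`, `p75`, `n_zero` and `pct_zero`.
#' @export
lpf_summary <- function(actual_days, predicted_days) {
  v <- lpf(actual_days, predicted_days)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], p25 = q[1], p75 = q[3],
       n_zero = sum(v == 0), pct_zero = 100 * mean(v == 0))
}

#' Root mean squared relative error
#'
#' Quadratic mean of the per-patient LPF values; 0 means every discharge day
#' was predicted exactly.
#'
#' @inheritParams lpf
#' @return nonnegative scalar.
#' @export
rmsre <- function(actual_days, predicted_days) {
  sqrt(mean(lpf(actual_days, predicted_days)^2))
}

#' Mann-Whitney U test (two-sided, normal approximation with tie correction)
#'
#' @param sample_a,sample_b numeric samples.
#' @return a `comparison_result`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop_icu("contract_violation", "samples must be nonempty")
  if (length(unique(c(sample_a, sample_b))) == 1)
    return(comparison_result("location", statistic = 0, p_value = 1,
                             method = "Mann-Whitney", estimate = 0))
  w <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = FALSE,
                                    correct = FALSE))
  comparison_result("location", statistic = unname(w$statistic),
                    p_value = w$p.value, method = "Mann-Whitney",
                    estimate = median(sample_a) - median(sample_b))
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param a,b events and non-events in the first group.
#' @param c,d events and non-events in the second group.
#' @return a `comparison_result`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_icu("contract_violation", "cells must be nonnegative integers")
  m <- matrix(cells, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_icu("undefined_metric", "chi-square undefined with a zero margin")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  comparison_result("proportion", statistic = unname(ct$statistic),
                    p_value = ct$p.value, method = "chi-square",
                    estimate = a / (a + b) - c / (c + d))
}

#' Discharge-day prevalence table
#'
#' Per discrete day: how many patients were actually discharged, how many
#' were predicted to be discharged, and how many were both (true positives).
#' Days at or beyond `cap` are pooled into one bucket.
#'
#' @inheritParams lpf
#' @param cap pooling day (default 14).
#' @return data frame with `day`, `n_actual`, `n_predicted`,
#'   `n_true_positive`; the last row pools days `>= cap`.
#' @export
prevalence_table <- function(actual_days, predicted_days, cap = 14L) {
  capd <- function(d) pmin(d, cap)
  a <- capd(actual_days)
  p <- capd(predicted_days)
  days <- 2:cap
  data.frame(
    day = c(as.character(days[-length(days)]), paste0(">=", cap)),
    n_actual = vapply(days, function(d) sum(a == d), integer(1)),
    n_predicted = vapply(days, function(d) sum(p == d), integer(1)),
    n_true_positive = vapply(days, function(d)
      sum(a == d & actual_days == predicted_days), integer(1)),
    stringsAsFactors = FALSE)
}

#' Best-discrimination cutoff on the ROC curve (Youden index)
#'
#' @param scores numeric predictions.
#' @param labels binary outcomes.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
roc_best_cutoff <- function(scores, labels) {
  y <- check_binary(labels)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  j <- sens + spec - 1
  i <- which.max(j)
  list(cutoff = thr[i], sensitivity = sens[i], specificity = spec[i],
       youden = j[i])
}

comparison_result <- function(metric, statistic, p_value, method,
                              estimate = NA_real_, models = c("a", "b")) {
  structure(list(metric = metric, models = models, statistic = statistic,
                 p_value = p_value, method = method, estimate = estimate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s): estimate %.4g, p = %.4g\n",
              x$metric, x$method, x$estimate, x$p_value))
  invisible(x)
}

#' Classification metric bundle for one prediction set
#'
#' @param probabilities second-day-discharge forecasts.
#' @param labels binary outcomes.
#' @param n_bins reliability-diagram bins.
#' @param hl_groups Hosmer-Lemeshow risk groups.
#' @return list with `aroc`, `brier`, `brier_scaled` (percent), `hl`
#'   (statistic/df/p), the Brier `decomposition`, and the Youden
#'   `best_cutoff`.
#' @export
classification_metrics <- function(probabilities, labels, n_bins = 10L,
                                   hl_groups = 10L) {
  y <- check_binary(labels)
  s <- mean(y)
  bs <- brier(probabilities, y)
  hl <- tryCatch(hosmer_lemeshow(probabilities, y, hl_groups),
                 icudischarge_undefined_metric = function(e)
                   list(statistic = NA_real_, df = NA, p_value = NA_real_))
  list(n = length(y), prevalence = s,
       aroc = auc(probabilities, y), brier = bs,
       brier_scaled = brier_scaled(bs, s), hl = hl,
       decomposition = brier_decomposition(probabilities, y, n_bins),
       best_cutoff = roc_best_cutoff(probabilities, y))
}

#' Regression metric bundle for one prediction set
#'
#' @param actual_days,predicted_days integer days `>= 2`.
#' @return list with actual/predicted median (P25-P75), the LPF summary,
#'   RMSRE, and the prevalence table.
#' @export
regression_metrics <- function(actual_days, predicted_days) {
  qa <- quantile(actual_days, c(0.25, 0.5, 0.75), names = FALSE)
  qp <- quantile(predicted_days, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(actual_days),
       actual = list(median = qa[2], p25 = qa[1], p75 = qa[3]),
       predicted = list(median = qp[2], p25 = qp[1], p75 = qp[3]),
       lpf = lpf_summary(actual_days, predicted_days),
       rmsre = rmsre(actual_days, predicted_days),
       prevalence = prevalence_table(actual_days, predicted_days))
}
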