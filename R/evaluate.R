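#' Median absolute deviation between predictions and actuals
#'
#' The prediction-error summary used throughout the harness: the median of
#' the per-subject absolute deviations |predicted - actual| (midpoint
#' convention at even n).
#'
#' @param pred,actual Equal-length numeric vectors.
#' @return A single nonnegative number.
#' @export
prediction_mad <- function(pred, actual) {
  if (length(pred) != length(actual)) abort("`pred` and `actual` must have equal length.")
  if (length(pred) < 1L) abort("Need at least one pair.")
  stats::median(abs(pred - actual))
}

#' Deviations under the chance ("zero-order") model
#'
#' The chance model predicts the sample mean for every subject; its
#' per-subject absolute deviations are |actual_i - mean(actual)|.
#'
#' @param actual Numeric vector, length >= 2.
#' @return Vector of absolute deviations from the mean.
#' @export
zero_order_deviations <- function(actual) {
  if (length(actual) < 2L) abort("Need n >= 2.")
  abs(actual - mean(actual))
}

# One-sided Wilcoxon signed-rank on paired differences `d`, zeros handled by
# the Pratt method (rank including zeros, then drop), average ranks for ties.
# For n <= exact_max_n the p-value is exact under the sign-permutation null,
# computed by convolving the rank generating function (this reproduces
# stats::psignrank in the tie-free case and stays exact under ties); beyond
# that, normal approximation with tie correction and continuity correction.
signed_rank_p <- function(d, alternative = c("greater", "less"),
                          exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  d <- d[is.finite(d)]
  N <- length(d)
  if (N < 1L) abort("No finite differences.")
  if (all(d == 0)) {
    warn("All paired differences are zero; p = 1.")
    return(1)
  }
  r <- rank(abs(d))              # Pratt: zeros keep their (low) ranks ...
  z <- sum(d == 0)
  keep <- d != 0                 # ... then drop out of the statistic
  w_pos <- sum(r[d > 0])
  if (N <= exact_max_n) {
    # exact distribution of W+ over the 2^m sign assignments of the nonzero
    # ranks; doubled ranks are integers even with average-rank ties
    r2 <- as.integer(round(2 * r[keep]))
    counts <- 1
    for (ri in r2) {
      padded <- c(counts, numeric(ri))
      counts <- padded + c(numeric(ri), counts)
    }
    w2 <- round(2 * w_pos)
    total <- sum(counts)
    if (alternative == "greater") {
      return(sum(counts[seq.int(w2 + 1L, length(counts))]) / total)
    }
    return(sum(counts[seq_len(w2 + 1L)]) / total)
  }
  mu <- (N * (N + 1) - z * (z + 1)) / 4
  tie_tab <- table(abs(d[keep]))
  sigma2 <- (N * (N + 1) * (2 * N + 1) - z * (z + 1) * (2 * z + 1)) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) {
    warn("Degenerate signed-rank variance; p = 1.")
    return(1)
  }
  if (alternative == "greater") {
    stats::pnorm((w_pos - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  } else {
    stats::pnorm((w_pos - mu + 0.5) / sqrt(sigma2))
  }
}

#' Compare a model against the chance model by paired Wilcoxon test
#'
#' Tests whether the model's per-subject absolute deviations are
#' systematically smaller than the chance (zero-order) model's, by a
#' one-sided paired Wilcoxon signed-rank test. This nonparametric choice is
#' robust to the non-normality and heteroscedasticity typical of bounded
#' clinical scores. By default the chance deviations are those of the actual
#' scores from the actual mean; `variant = "predicted_mean"` uses the
#' literal alternative reading (deviations of the predictions from their own
#' mean).
#'
#' @param pred,actual Equal-length numeric vectors, n >= 5.
#' @param variant `"actual_mean"` (default) or `"predicted_mean"`.
#' @return One-sided p-value (small = model beats chance).
#' @export
compare_to_zero_order <- function(pred, actual,
                                  variant = c("actual_mean", "predicted_mean")) {
  variant <- match.arg(variant)
  if (length(pred) != length(actual)) abort("`pred` and `actual` must have equal length.")
  if (length(pred) < 5L) abort("Need n >= 5 for the paired comparison.")
  model_dev <- abs(pred - actual)
  chance_dev <- switch(variant,
                       actual_mean = zero_order_deviations(actual),
                       predicted_mean = abs(pred - mean(pred)))
  signed_rank_p(model_dev - chance_dev, alternative = "less")
}

#' Squared Pearson correlation with a one-sided hypothesis test
#'
#' R^2 as the squared Pearson correlation between predicted and actual
#' values, with a one-sided test that the correlation exceeds zero
#' (t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom).
#'
#' @param pred,actual Equal-length numeric vectors, n >= 3.
#' @return List with `r_squared`, `p_value`, and the signed `correlation`.
#'   A constant vector gives r_squared = 0 and p = 1 with a warning.
#' @export
r_squared_with_test <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) < 3L) {
    abort("Need equal-length vectors with n >= 3.")
  }
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0) {
    warn("Constant vector: correlation undefined; reporting R^2 = 0, p = 1.")
    return(list(r_squared = 0, p_value = 1, correlation = NA_real_))
  }
  ct <- stats::cor.test(pred, actual, alternative = "greater")
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
       correlation = unname(ct$estimate))
}

#' Case-resampling percentile bootstrap confidence interval
#'
#' Resamples (predicted, actual) pairs with replacement, recomputes the
#' metric on each replicate, and returns the 2.5th and 97.5th percentiles.
#' Degenerate replicates (metric undefined, e.g. a constant resample for a
#' correlation metric) are skipped and counted; more than 20% of them is an
#' error.
#'
#' @param metric Function `(pred, actual) -> scalar`.
#' @param pred,actual Equal-length numeric vectors, n >= 5.
#' @param n_boot Number of replicates (default 2000).
#' @param seed Integer seed.
#' @param conf Coverage (default 0.95).
#' @return Named numeric `c(lower, upper)` with attribute `n_degenerate`.
#' @export
bootstrap_ci <- function(metric, pred, actual, n_boot = 2000L, seed = 1L,
                         conf = 0.95) {
  n <- length(pred)
  if (n != length(actual) || n < 5L) abort("Need equal-length vectors with n >= 5.")
  n_boot <- check_count(n_boot, "n_boot")
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(suppressWarnings(metric(pred[idx], actual[idx])),
                    error = function(e) NA_real_)
      if (is.list(v)) v <- v[[1]]
      as.double(v)
    }, numeric(1))
  })
  bad <- !is.finite(vals)
  if (mean(bad) > 0.2) {
    abort(sprintf("%.0f%% of bootstrap replicates were degenerate; the interval is unreliable.",
                  100 * mean(bad)))
  }
  q <- stats::quantile(vals[!bad], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  structure(c(lower = q[1], upper = q[2]), n_degenerate = sum(bad))
}

#' One-sided treatment-effect test on paired pre/post scores
#'
#' Wilcoxon signed-rank test that post-treatment scores exceed pre-treatment
#' scores (alternative: post > pre), with Pratt handling of zero
#' differences.
#'
#' @param pre,post Equal-length numeric vectors, n >= 5.
#' @return One-sided p-value.
#' @export
treatment_effect_test <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` must have equal length.")
  if (length(pre) < 5L) abort("Need n >= 5 pairs.")
  signed_rank_p(post - pre, alternative = "greater")
}

#' Full model-assessment report
#'
#' Bundles the harness: MAD with bootstrap CI, the paired Wilcoxon
#' comparison against the chance model, and R^2 with its correlation test
#' and bootstrap CI.
#'
#' @param pred,actual Equal-length numeric vectors (LOOCV predictions and
#'   observed outcomes), n >= 5.
#' @param n_boot,seed Bootstrap settings, see [bootstrap_ci()].
#' @param variant Chance-model variant, see [compare_to_zero_order()].
#' @return Object of class `model_evaluation` with fields `mad`, `mad_ci95`,
#'   `wilcoxon_p_vs_zero_order`, `r_squared`, `r_squared_ci95`,
#'   `correlation_test_p`, `n`.
#' @export
evaluate_predictions <- function(pred, actual, n_boot = 2000L, seed = 1L,
                                 variant = "actual_mean") {
  r2 <- suppressWarnings(r_squared_with_test(pred, actual))
  structure(
    list(mad = prediction_mad(pred, actual),
         mad_ci95 = bootstrap_ci(prediction_mad, pred, actual, n_boot,
                                 seed = derive_seed(seed, 1L, 41L)),
         wilcoxon_p_vs_zero_order = compare_to_zero_order(pred, actual,
                                                          variant = variant),
         r_squared = r2$r_squared,
         r_squared_ci95 = bootstrap_ci(function(p, a) r_squared_with_test(p, a)$r_squared,
                                       pred, actual, n_boot,
                                       seed = derive_seed(seed, 2L, 41L)),
         correlation_test_p = r2$p_value,
         n = length(pred)),
    class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("<model_evaluation> n = %d\n",
           "  MAD = %.3f (95%% CI %.3f-%.3f), vs chance p = %.3g\n",
           "  R^2 = %.3f (95%% CI %.3f-%.3f), correlation test p = %.3g\n"),
    x$n, x$mad, x$mad_ci95[1], x$mad_ci95[2], x$wilcoxon_p_vs_zero_order,
    x$r_squared, x$r_squared_ci95[1], x$r_squared_ci95[2], x$correlation_test_p))
  invisible(x)
}

#' @rdname tidy_falffprog
#' @export
glance.model_evaluation <- function(x, ...) {
  tibble(n = x$n, mad = x$mad,
         mad_ci_lower = x$mad_ci95[[1]], mad_ci_upper = x$mad_ci95[[2]],
         wilcoxon_p_vs_zero_order = x$wilcoxon_p_vs_zero_order,
         r_squared = x$r_squared,
         r_squared_ci_lower = x$r_squared_ci95[[1]],
         r_squared_ci_upper = x$r_squared_ci95[[2]],
         correlation_test_p = x$correlation_test_p)
}
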