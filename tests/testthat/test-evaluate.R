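test_that("prediction MAD follows the median-of-absolute-deviations definition", {
  expect_equal(prediction_mad(c(0.5, 0.6, 0.7), c(0.4, 0.8, 0.7)), 0.1)
  expect_equal(prediction_mad(1:5 / 10, 1:5 / 10), 0)
  expect_equal(prediction_mad(c(0.1, 0.3), c(0, 0)), 0.2)   # even-n midpoint
  expect_error(prediction_mad(1:3, 1:4), "equal length")
  # translation invariance and scale equivariance
  set.seed(61)
  p <- runif(9); a <- runif(9)
  expect_equal(prediction_mad(p + 0.3, a + 0.3), prediction_mad(p, a))
  expect_equal(prediction_mad(2.5 * p, 2.5 * a), 2.5 * prediction_mad(p, a))
})

test_that("zero-order deviations are distances to the sample mean", {
  expect_equal(zero_order_deviations(c(0.2, 0.4, 0.6)), c(0.2, 0, 0.2))
  expect_equal(zero_order_deviations(rep(0.5, 4)), rep(0, 4))
  expect_equal(median(zero_order_deviations(c(0, 1))), 0.5)
})

test_that("uniformly better models reach the exact all-positive signed-rank bound", {
  # n = 20: every model deviation smaller than chance by a distinct margin
  actual <- seq(0.05, 0.95, length.out = 20)
  zd <- zero_order_deviations(actual)
  delta <- seq(0.001, 0.004, length.out = 20)
  pred <- actual + pmax(zd - delta, 0)
  expect_equal(compare_to_zero_order(pred, actual), 1 / 2^20)

  actual10 <- seq(0.1, 0.9, length.out = 10)
  zd10 <- zero_order_deviations(actual10)
  pred10 <- actual10 + pmax(zd10 - seq(0.001, 0.003, length.out = 10), 0)
  expect_equal(compare_to_zero_order(pred10, actual10), 1 / 2^10)

  # identical deviations: no evidence (binary-fraction scores keep the
  # floating-point arithmetic exact)
  actual_b <- c(0.25, 0.75, 0.25, 0.75, 0.5, 0.5)
  pred_same <- actual_b + zero_order_deviations(actual_b)
  expect_warning(p <- compare_to_zero_order(pred_same, actual_b), "zero")
  expect_equal(p, 1)
})

test_that("exact signed-rank agrees with full sign enumeration for n <= 10", {
  set.seed(62)
  for (rep in 1:15) {
    n <- sample(5:10, 1)
    actual <- runif(n)
    pred <- actual + runif(n, -0.3, 0.3)
    d <- abs(pred - actual) - zero_order_deviations(actual)
    if (any(d == 0) || any(duplicated(abs(d)))) next
    expect_equal(compare_to_zero_order(pred, actual),
                 oracle_signed_rank_p(d, "less"), tolerance = 1e-12)
  }
  # and for the treatment-effect direction
  for (rep in 1:10) {
    n <- 7
    pre <- runif(n); post <- pre + runif(n, -0.2, 0.3)
    d <- post - pre
    if (any(d == 0) || any(duplicated(abs(d)))) next
    expect_equal(treatment_effect_test(pre, post),
                 oracle_signed_rank_p(d, "greater"), tolerance = 1e-12)
  }
})

test_that("the chance-model p-value falls as the model improves", {
  actual <- seq(0.1, 0.9, length.out = 12)
  zd <- zero_order_deviations(actual)
  set.seed(64)
  e <- runif(12, -0.08, 0.08)   # a mixed starting model
  ps <- vapply(c(0, 0.04, 0.08), function(gain) {
    pred <- actual + pmax(zd + e - gain, 0)
    compare_to_zero_order(pred, actual)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_lt(ps[3], ps[1])
  # literal-reading variant is available and differs in general
  pred <- actual + 0.5 * zd
  expect_false(isTRUE(all.equal(
    compare_to_zero_order(pred, actual),
    compare_to_zero_order(pred, actual, variant = "predicted_mean"))))
})

test_that("R^2 is squared Pearson with a one-sided t test", {
  a <- c(0.2, 0.4, 0.5, 0.7, 0.9)
  perfect <- r_squared_with_test(a, a)
  expect_equal(perfect$r_squared, 1)
  expect_lt(perfect$p_value, 1e-10)
  flipped <- r_squared_with_test(-a, a)
  expect_equal(flipped$r_squared, 1)
  expect_gt(flipped$p_value, 0.99)

  set.seed(63)
  p <- runif(5); q <- p + rnorm(5, sd = 0.2)
  got <- r_squared_with_test(p, q)
  r <- sum(scale(p) * scale(q)) / 4
  t_stat <- r * sqrt(3 / (1 - r^2))
  expect_equal(got$r_squared, r^2, tolerance = 1e-6)
  expect_equal(got$p_value, pt(t_stat, 3, lower.tail = FALSE), tolerance = 1e-6)

  expect_warning(const <- r_squared_with_test(rep(0.5, 5), a), "Constant")
  expect_equal(const$r_squared, 0)
  expect_equal(const$p_value, 1)

  # affine invariance with positive slope; sidedness flips with negative slope
  expect_equal(r_squared_with_test(2 * p + 1, q)$r_squared, got$r_squared,
               tolerance = 1e-12)
  expect_equal(r_squared_with_test(-2 * p, q)$r_squared, got$r_squared,
               tolerance = 1e-12)
  expect_gt(r_squared_with_test(-2 * p, q)$p_value, 1 - got$p_value - 1e-9)
})

test_that("bootstrap intervals are seeded, collapse for perfect models, and cover", {
  a <- seq(0.1, 0.9, length.out = 12)
  ci <- bootstrap_ci(prediction_mad, a, a, n_boot = 200, seed = 5)
  expect_equal(as.numeric(ci), c(0, 0))
  set.seed(65)
  b <- a + rnorm(12, sd = 0.05)
  ci2 <- bootstrap_ci(prediction_mad, a, b, n_boot = 200, seed = 5)
  ci3 <- bootstrap_ci(prediction_mad, a, b, n_boot = 200, seed = 5)
  expect_identical(ci2, ci3)
  expect_lte(ci2[[1]], ci2[[2]])

  # nominal 95% coverage of a known population R^2 (rho = 0.6, n = 50)
  cover <- 0; sims <- 200
  for (s in seq_len(sims)) {
    set.seed(7000 + s)
    x <- rnorm(50); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(50)
    ci <- bootstrap_ci(function(p, q) suppressWarnings(r_squared_with_test(p, q))$r_squared,
                       x, y, n_boot = 400, seed = s)
    cover <- cover + (ci[[1]] <= 0.36 && 0.36 <= ci[[2]])
  }
  expect_lt(abs(cover / sims - 0.95), 0.04)
})

test_that("the treatment-effect test is one-sided for improvement", {
  pre <- seq(0.2, 0.65, length.out = 10)
  expect_equal(treatment_effect_test(pre, pre + 0.1), 1 / 2^10)
  expect_warning(p <- treatment_effect_test(pre, pre), "zero")
  expect_equal(p, 1)
})

test_that("the full evaluation report is internally consistent", {
  fit <- recovery_fit()
  ev <- evaluate_predictions(fit$predictions$predicted, fit$predictions$actual,
                             n_boot = 500, seed = 2)
  expect_lte(ev$mad_ci95[[1]], ev$mad)
  expect_gte(ev$mad_ci95[[2]], ev$mad)
  expect_lte(ev$r_squared_ci95[[1]], ev$r_squared + 1e-12)
  expect_gte(ev$r_squared_ci95[[2]], ev$r_squared - 1e-12)
  expect_equal(ev$n, 30)
  g <- glance(ev)
  expect_equal(g$r_squared, ev$r_squared)
})
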