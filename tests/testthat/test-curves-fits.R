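test_that("curve binning follows the closure and accounting rules", {
  cv <- build_curve(rep(0.5, 10), success = rep(c(TRUE, FALSE), c(7, 3)))
  nz <- cv$counted > 0
  expect_identical(sum(nz), 1L)
  expect_equal(cv$probability[nz], 0.7)
  # a frequency of exactly 1 lands in the (closed) last bin
  cv2 <- build_curve(c(0, 0.999, 1, 1), success = c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(cv2$counted[100], 3L)
  expect_identical(cv2$counted[1], 1L)
  expect_identical(sum(cv2$counted), 4L)
  # totals are conserved and uncounted events are dropped
  set.seed(41)
  x <- runif(500)
  counted <- runif(500) < 0.8
  cv3 <- build_curve(x, counted, counted & (runif(500) < 0.5))
  expect_identical(sum(cv3$counted), sum(counted))
  expect_error(build_curve(numeric(0), success = logical(0)), "empty curve")
  expect_error(build_curve(0.5, success = TRUE, bin_width = 0.03),
               "bin_width")
})

test_that("the weighted linear fit is exact on exact lines", {
  x <- seq(0.05, 0.95, by = 0.1)
  f1 <- fit_linear(synthetic_curve(x, 0.2 * x))
  expect_equal(unname(f1$coefficients), c(0, 0.2), tolerance = 1e-8)
  expect_equal(f1$r_squared, 1)
  f2 <- fit_linear(synthetic_curve(x, 1 - x))
  expect_equal(unname(f2$coefficients), c(1, -1), tolerance = 1e-8)
  expect_equal(f2$r_squared, 1)
  # zero-variance data: slope 0 and r2 = 1 by the zero-residual convention
  f3 <- fit_linear(synthetic_curve(x, rep(0.4, length(x))))
  expect_equal(f3$coefficients[["slope"]], 0, tolerance = 1e-8)
  expect_equal(f3$r_squared, 1)
  expect_error(fit_linear(synthetic_curve(0.5, 0.5)), "underdetermined")
})

test_that("the logistic fit recovers known parameters from clean data", {
  x <- seq(0.005, 0.995, length.out = 101)
  y <- stats::plogis(-5 + 10 * x)
  fit <- fit_sigmoid(synthetic_curve(x, y, rep(10000L, 101)))
  expect_true(fit$converged)
  expect_equal(fit$coefficients[["a"]], -5, tolerance = 0.01)
  expect_equal(fit$coefficients[["b"]], 10, tolerance = 0.01)
  expect_error(fit_sigmoid(synthetic_curve(c(0.2, 0.8), c(0.2, 0.8))),
               "underdetermined")
})

test_that("the frequency-bias fit is neutral at theta = 1", {
  x <- seq(0.05, 0.95, by = 0.1)
  fit <- fit_sigmoid(synthetic_curve(x, x), form = "freq_bias")
  expect_equal(fit$coefficients[["theta"]], 1, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
})

test_that("step-shaped data favour the sigmoid, exact lines the linear model", {
  x <- seq(0.05, 0.95, by = 0.1)
  step <- ifelse(x < 0.5, 0.2, 1.0)
  cmp_step <- compare_fits(synthetic_curve(x, step))
  expect_identical(cmp_step$better, "sigmoid")
  expect_gt(cmp_step$sigmoid$r_squared, cmp_step$linear$r_squared)
  # both models reach r2 = 1 on an exact line; the tie resolves to linear
  cmp_line <- compare_fits(synthetic_curve(x, x))
  expect_identical(cmp_line$better, "linear")
  cmp_logi <- compare_fits(synthetic_curve(x, stats::plogis(-10 + 20 * x)))
  expect_identical(cmp_logi$better, "sigmoid")
})

test_that("an unavailable sigmoid fit degrades to a flagged linear-only comparison", {
  two_bins <- synthetic_curve(c(0.25, 0.75), c(0.3, 0.6))
  expect_warning(cmp <- compare_fits(two_bins), "sigmoid")
  expect_identical(cmp$better, "linear")
  expect_false(cmp$sigmoid_ok)
  expect_true(is.na(cmp$relative_fit))
})
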