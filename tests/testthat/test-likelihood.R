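# A curve whose observations sit exactly on the model prediction, plus a
# helper to shift residuals by hand.
perfect_curve <- function(params, times) {
  growth_curve(data.frame(time = times, logc = growth_predict(times, params)))
}

test_that("gaussian log-likelihood matches direct arithmetic", {
  p <- base_params()
  times <- c(0, 10, 20, 40, 60)
  cv <- perfect_curve(p, times)
  # residuals all zero: -N ln(sqrt(2 pi))
  expect_equal(loglik_gaussian(cv, p, sigma = 1), -5 * log(sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(loglik_gaussian(cv, p, sigma = 1), -4.5946927,
               tolerance = 1e-6)
  # one point with residual 2, sigma 1: -ln(sqrt(2 pi)) - 2
  one <- growth_curve(data.frame(time = c(0, 10),
                                 logc = growth_predict(c(0, 10), p) + c(0, 2)))
  expect_equal(loglik_gaussian(one, p, sigma = 1),
               -2 * log(sqrt(2 * pi)) - 2, tolerance = 1e-12)
  # zero residual, sigma 0.5: -ln(0.5 sqrt(2 pi)) per point
  expect_equal(loglik_gaussian(perfect_curve(p, c(0, 10)), p, sigma = 0.5),
               2 * -0.2257914, tolerance = 1e-6)
  expect_error(loglik_gaussian(cv, p, sigma = 0), "positive")
})

test_that("gaussian log-likelihood is maximized at the mean squared residual", {
  p <- base_params()
  withr::with_seed(3, {
    cv <- simulate_growth_curve(p, sigma = 0.2, seed = 5)
    resid <- cv$logc - growth_predict(cv$time, p)
    s_hat <- sqrt(mean(resid^2))
    ll_hat <- loglik_gaussian(cv, p, s_hat)
    for (s in c(0.5, 0.9, 1.1, 2) * s_hat) {
      expect_lt(loglik_gaussian(cv, p, s), ll_hat)
    }
  })
})

test_that("censored-point log-likelihood is the uniform density with a tail", {
  expect_equal(loglik_censored_point(0.4, 1.3, 0.1), log(1 / 1.3),
               tolerance = 1e-12)
  expect_equal(loglik_censored_point(0.4, 1.3, 0.1), -0.2623643,
               tolerance = 1e-6)
  # continuous at the threshold
  expect_equal(loglik_censored_point(1.3, 1.3, 0.1), log(1 / 1.3),
               tolerance = 1e-12)
  # tail: (0.2)^2 / (2 * 0.01) = 2 below the boundary value
  expect_equal(loglik_censored_point(1.5, 1.3, 0.1), log(1 / 1.3) - 2,
               tolerance = 1e-12)
  # continuity at the boundary and monotone decay above the threshold
  expect_equal(loglik_censored_point(1.3 + 1e-9, 1.3, 0.1),
               loglik_censored_point(1.3, 1.3, 0.1), tolerance = 1e-12)
  v <- loglik_censored_point(seq(1.29, 2, by = 0.001), 1.3, 0.1)
  expect_true(all(diff(v) <= 0))
  expect_error(loglik_censored_point(1, -1, 0.1), "threshold")
  expect_error(loglik_censored_point(1, 1.3, 0), "tail_sd")
})

test_that("curve log-likelihood splits into gaussian and censored parts", {
  p <- base_params()
  cv <- perfect_curve(p, c(0, 10, 20, 40))
  expect_identical(loglik_curve(cv, p, sigma = 1),
                   loglik_gaussian(cv, p, sigma = 1))
  # three exact points plus one censored point predicted below threshold:
  # build a curve whose first observation is below detection
  p_low <- growth_params(0.2, 0.11, 1, 6)
  times <- c(0, 30, 45, 60)
  pred <- growth_predict(times, p_low)
  df <- data.frame(time = times, logc = c(pred[1], pred[-1]),
                   censored = c(TRUE, FALSE, FALSE, FALSE))
  cv_mixed <- growth_curve(df, threshold = 1.3)
  expect_equal(loglik_curve(cv_mixed, p_low, sigma = 1),
               -3 * log(sqrt(2 * pi)) + log(1 / 1.3), tolerance = 1e-12)
  expect_equal(loglik_curve(cv_mixed, p_low, sigma = 1), -3.0191798,
               tolerance = 1e-6)
  # all censored, model below threshold: N * ln(1/T)
  df_all <- data.frame(time = c(0, 2), logc = c(0.2, 0.3),
                       censored = c(TRUE, TRUE))
  cv_all <- growth_curve(df_all, threshold = 1.3)
  expect_equal(loglik_curve(cv_all, growth_params(0.1, 0.01, 1, 5), 1),
               2 * log(1 / 1.3), tolerance = 1e-10)
})

test_that("curve log-likelihood decreases as any residual grows", {
  p <- base_params()
  times <- seq(0, 60, length.out = 8)
  base_vals <- growth_predict(times, p)
  for (i in c(1, 4, 8)) {
    lls <- vapply(c(0, 0.5, 1, 2), function(shift) {
      vals <- base_vals
      vals[i] <- vals[i] + shift
      loglik_curve(growth_curve(data.frame(time = times, logc = vals)), p, 0.3)
    }, numeric(1))
    expect_true(all(diff(lls) < 0))
  }
})

test_that("joint log-likelihood is additive and symmetric", {
  pa <- base_params()
  pb <- growth_params(4, 0.2, 0.5, 8)
  ca <- perfect_curve(pa, c(0, 10, 20, 40))
  cb <- perfect_curve(pb, c(0, 5, 15, 30))
  expect_equal(loglik_joint(ca, ca, pa, pa, 1), 2 * loglik_curve(ca, pa, 1),
               tolerance = 1e-12)
  expect_equal(loglik_joint(ca, cb, pa, pb, 0.4),
               loglik_joint(cb, ca, pb, pa, 0.4), tolerance = 1e-12)
  # two perfect 4-point curves, sigma 1: -8 ln(sqrt(2 pi))
  expect_equal(loglik_joint(ca, cb, pa, pb, 1), -8 * log(sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(loglik_joint(ca, cb, pa, pb, 1), -7.3515081, tolerance = 1e-6)
})

test_that("compiled curve log-likelihood agrees with the public functions", {
  p <- base_params()
  cv <- simulate_growth_curve(p, sigma = 0.15, seed = 9)
  ll <- growthbayes:::.compile_curve_loglik(cv)
  th <- c(p$y0, p$mu_max, p$h0, p$ymax)
  expect_equal(ll(th, 0.2), loglik_curve(cv, p, 0.2), tolerance = 1e-12)
})
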