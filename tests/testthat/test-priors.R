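test_that("data-scaled default bounds follow the stated rules", {
  cv <- growth_curve(data.frame(time = c(0, 10, 20), logc = c(3, 6, 9)))
  sp <- default_priors(cv)
  expect_equal(c(sp$y0$lower, sp$y0$upper), c(0, 9))
  expect_equal(c(sp$ymax$lower, sp$ymax$upper), c(3, 12))
  expect_equal(sp$mu_max$lower, 1e-6)
  expect_equal(sp$mu_max$upper, 3)  # 10 * r / t_span = 10 * 6 / 20
  expect_equal(c(sp$h0$lower, sp$h0$upper), c(0, 60))
  expect_identical(sp$sigma$dist, "jeffreys")
  expect_equal(c(sp$sigma$lower, sp$sigma$upper), c(1e-3, 6))
  # degenerate constant curve: range floored at 1, no error
  flat <- growth_curve(data.frame(time = c(0, 5, 10), logc = c(4, 4, 4)))
  sp_flat <- default_priors(flat)
  expect_equal(c(sp_flat$y0$lower, sp_flat$y0$upper), c(3.5, 4))
  expect_equal(sp_flat$mu_max$upper, 1)
  # restricted variants drop entries; fixed noise drops sigma
  expect_named(default_priors(cv, model = "exponential", sigma = "fixed"),
               c("y0", "mu_max"))
})

test_that("prior transform maps the cube as the inverse CDF", {
  expect_equal(unname(prior_transform(0.5, prior_spec(x = prior_uniform(0, 4)))),
               2)
  expect_equal(
    unname(prior_transform(0.5, prior_spec(s = prior_jeffreys(1e-3, 10)))),
    0.1, tolerance = 1e-12
  )
  expect_equal(
    unname(prior_transform(0.5,
                           prior_spec(x = prior_gaussian(0, 1, -2, 2)))),
    0, tolerance = 1e-12
  )
  expect_error(prior_transform(1.5, prior_spec(x = prior_uniform(0, 1))),
               "unit hypercube")
  expect_error(prior_transform(c(0.1, 0.2),
                               prior_spec(x = prior_uniform(0, 1))),
               "one component")
})

test_that("transform round-trips through each entry's CDF", {
  entries <- list(
    prior_uniform(-3, 7),
    prior_jeffreys(1e-3, 2),
    prior_gaussian(0.1, 0.05, 0, 0.5),
    prior_cauchy(0.1, 0.05, 0, 0.5)
  )
  u <- seq(0.001, 0.999, length.out = 21)
  for (e in entries) {
    x <- growthbayes:::.entry_transform(e, u)
    expect_equal(growthbayes:::.entry_cdf(e, x), u, tolerance = 1e-9)
    expect_true(all(diff(x) > 0))  # monotone
    expect_true(all(x >= e$lower & x <= e$upper))
  }
})

test_that("each prior density integrates to one over its support", {
  entries <- list(
    prior_uniform(-3, 7),
    prior_jeffreys(1e-3, 2),
    prior_gaussian(0.1, 0.05, 0, 0.5),
    prior_cauchy(0.1, 0.05, 0, 0.5)
  )
  for (e in entries) {
    z <- stats::integrate(function(x) exp(growthbayes:::.entry_logdens(e, x)),
                          e$lower, e$upper, rel.tol = 1e-9)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("log prior density sums entries and enforces ymax > y0", {
  sp <- prior_spec(y0 = prior_uniform(0, 4), ymax = prior_uniform(0, 12))
  expect_equal(log_prior_density(c(y0 = 2, ymax = 6), sp),
               log(1 / 4) + log(1 / 12), tolerance = 1e-12)
  expect_identical(log_prior_density(c(y0 = 3, ymax = 2), sp), -Inf)
  expect_identical(
    log_prior_density(c(y0 = 5, ymax = 6), sp), -Inf  # outside y0 support
  )
  g <- prior_spec(x = prior_gaussian(0, 1, -1, 1))
  expect_equal(log_prior_density(c(x = 0), g),
               log(dnorm(0) / (pnorm(1) - pnorm(-1))), tolerance = 1e-12)
})

test_that("cluster priors follow the law of total variance", {
  # single member collapses to its own summary
  one <- cluster_prior(data.frame(mean = 0.12, variance = 4e-4))
  expect_equal(one$mean, 0.12)
  expect_equal(one$sd^2, 4e-4, tolerance = 1e-12)
  # two-member worked value
  two <- cluster_prior(data.frame(mean = c(0.1, 0.2),
                                  variance = c(1e-4, 4e-4)))
  expect_equal(two$mean, 0.15)
  expect_equal(two$sd^2, 0.00275, tolerance = 1e-12)
  # N identical members: between-member term vanishes
  same <- cluster_prior(data.frame(mean = rep(0.13, 4),
                                   variance = rep(2e-4, 4)))
  expect_equal(same$mean, 0.13)
  expect_equal(same$sd^2, 2e-4, tolerance = 1e-12)
  # Monte-Carlo oracle: variance of the equal-weight gaussian mixture
  withr::with_seed(21, {
    comp <- sample(1:2, 2e5, replace = TRUE)
    draws <- rnorm(2e5, mean = c(0.1, 0.2)[comp], sd = sqrt(c(1e-4, 4e-4))[comp])
    expect_equal(var(draws), 0.00275, tolerance = 0.01)
  })
  # cauchy uses the same location/scale rule
  twc <- cluster_prior(data.frame(mean = c(0.1, 0.2),
                                  variance = c(1e-4, 4e-4)), kind = "cauchy")
  expect_identical(twc$dist, "cauchy")
  expect_equal(twc$location, 0.15)
  expect_equal(twc$scale^2, 0.00275, tolerance = 1e-12)
  expect_error(cluster_prior(data.frame(mean = numeric(), variance = numeric())),
               "at least one")
})

test_that("cauchy tails are heavier than gaussian tails at the same scale", {
  g <- prior_gaussian(0.13, 0.01, 0.01, 0.5)
  c_ <- prior_cauchy(0.13, 0.01, 0.01, 0.5)
  offsets <- c(0.05, 0.1, 0.2, 0.3)
  ratio <- vapply(offsets, function(d) {
    growthbayes:::.entry_logdens(c_, 0.13 + d) -
      growthbayes:::.entry_logdens(g, 0.13 + d)
  }, numeric(1))
  expect_true(all(ratio > 0))
  expect_true(all(diff(ratio) > 0))  # grows toward the bounds
})

test_that("prior entries validate their fields", {
  expect_error(prior_uniform(2, 1), "lower < upper")
  expect_error(prior_gaussian(0, -1), "positive")
  expect_error(prior_cauchy(0, 0), "positive")
  expect_error(prior_jeffreys(-1, 2), "strictly positive")
  expect_error(prior_spec(prior_uniform(0, 1)), "named")
})
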