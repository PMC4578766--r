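test_that("constant likelihood recovers the constant exactly", {
  sp <- prior_spec(x = prior_uniform(0, 1))
  r <- nested_sample(function(th) 1.5, sp,
                     ns_config(n_live = 30, seed = 1, max_iterations = 2000))
  expect_equal(r$log_evidence, 1.5, tolerance = 1e-9)
  expect_true(r$converged)
})

test_that("1-D and 2-D gaussian toys recover the analytic evidence", {
  sp1 <- prior_spec(x = prior_uniform(-10, 10))
  r1 <- nested_sample(function(th) dnorm(th[1], log = TRUE), sp1,
                      ns_config(n_live = 200, seed = 3))
  expect_equal(r1$log_evidence, log(1 / 20), tolerance = 0.1)
  sp2 <- prior_spec(x = prior_uniform(-10, 10), y = prior_uniform(-10, 10))
  r2 <- nested_sample(function(th) sum(dnorm(th, log = TRUE)), sp2,
                      ns_config(n_live = 200, seed = 3))
  expect_equal(r2$log_evidence, 2 * log(1 / 20), tolerance = 0.06)
})

test_that("shrinkage bookkeeping: widths plus final prior mass sum to one", {
  sp <- prior_spec(x = prior_uniform(-5, 5))
  r <- nested_sample(function(th) dnorm(th[1], sd = 0.3, log = TRUE), sp,
                     ns_config(n_live = 40, seed = 2))
  k <- r$n_iterations
  n <- r$n_live
  # deterministic schedule X_k = exp(-k/n)
  dead_w <- exp(r$samples$log_width[seq_len(k)])
  expect_equal(dead_w, exp(-(seq_len(k) - 1) / n) - exp(-seq_len(k) / n),
               tolerance = 1e-9)
  expect_equal(sum(exp(r$samples$log_width)), 1, tolerance = 1e-9)
  # removed-point log-likelihoods are non-decreasing
  expect_true(all(diff(r$samples$log_lik[seq_len(k)]) >= 0))
  # weights are normalized
  expect_equal(sum(r$samples$weight), 1, tolerance = 1e-6)
  expect_true(all(r$samples$weight >= 0))
})

test_that("runs are reproducible given a seed and flag the iteration cap", {
  sp <- prior_spec(x = prior_uniform(-10, 10))
  ll <- function(th) dnorm(th[1], log = TRUE)
  a <- nested_sample(ll, sp, ns_config(n_live = 50, seed = 7))
  b <- nested_sample(ll, sp, ns_config(n_live = 50, seed = 7))
  expect_identical(a$log_evidence, b$log_evidence)
  expect_identical(a$samples, b$samples)
  capped <- nested_sample(ll, sp,
                          ns_config(n_live = 50, seed = 7,
                                    max_iterations = 60))
  expect_false(capped$converged)
})

test_that("initialization fails loudly when the prior has no support", {
  sp <- prior_spec(x = prior_uniform(0, 1))
  expect_error(
    nested_sample(function(th) -Inf, sp, ns_config(n_live = 10, seed = 1)),
    "zero likelihood"
  )
})

test_that("posterior summaries match hand arithmetic", {
  r1 <- fake_ns_result(values = 2.5, weights = 1)
  s1 <- posterior_summary(r1)
  expect_equal(s1$mean, 2.5)
  expect_equal(s1$sd, 0)
  r2 <- fake_ns_result(values = c(0, 2), weights = c(0.5, 0.5))
  s2 <- posterior_summary(r2)
  expect_equal(s2$mean, 1)
  expect_equal(s2$sd, 1)
  r3 <- fake_ns_result(values = c(0, 4), weights = c(0.75, 0.25))
  s3 <- posterior_summary(r3)
  expect_equal(s3$mean, 1)
  expect_equal(s3$sd, sqrt(3), tolerance = 1e-12)
})

test_that("staircase sampling resamples proportionally to the weights", {
  # all weight on one sample
  point <- fake_ns_result(values = c(1, 9), weights = c(1, 0))
  draws <- staircase_sample(point, 100, seed = 1)
  expect_true(all(draws$p == 1))
  # equal weights: binomial 99% band at 1e4 draws
  even <- fake_ns_result(values = c(0, 1), weights = c(0.5, 0.5))
  draws <- staircase_sample(even, 1e4, seed = 2)
  expect_gt(mean(draws$p), 0.5 - 2.58 * 0.005)
  expect_lt(mean(draws$p), 0.5 + 2.58 * 0.005)
  # determinism
  expect_identical(staircase_sample(even, 50, seed = 3),
                   staircase_sample(even, 50, seed = 3))
  expect_error(staircase_sample(even, 0), "positive")
})

test_that("staircase mean agrees with the weighted posterior mean", {
  sp <- prior_spec(x = prior_uniform(-10, 10))
  r <- nested_sample(function(th) dnorm(th[1], mean = 1.2, log = TRUE), sp,
                     ns_config(n_live = 100, seed = 5))
  ps <- posterior_summary(r)
  draws <- staircase_sample(r, 1e4, seed = 9)
  se <- ps$sd / sqrt(1e4)
  expect_lt(abs(mean(draws$x) - ps$mean), 3 * se + 1e-3)
})

test_that("constrained draws respect the likelihood floor and the prior", {
  sp <- prior_spec(x = prior_uniform(0, 2))
  ll <- function(th) dnorm(th[1], mean = 1, sd = 0.3, log = TRUE)
  withr::with_seed(11, {
    live_u <- matrix(runif(40), ncol = 1)
    live_l <- apply(live_u, 1, function(u) ll(2 * u))
    l_star <- sort(live_l)[10]
    for (i in 1:20) {
      d <- constrained_draw(live_u, live_l, l_star, ll, sp,
                            ns_config(n_live = 40), step = 0.2)
      expect_gt(d$loglik, l_star)
      expect_true(d$theta >= 0 && d$theta <= 2)
    }
  })
  # flat likelihood: the walk's marginal matches the prior (KS test)
  flat <- function(th) 1
  draws <- withr::with_seed(13, {
    live_u <- matrix(runif(40), ncol = 1)
    live_l <- rep(1, 40)
    vapply(1:600, function(i) {
      constrained_draw(live_u, live_l, 0, flat, sp,
                       ns_config(n_live = 40, max_mcmc_steps = 60),
                       step = 0.6)$theta
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 0, 2))
  expect_gt(ks$p.value, 0.01)
  # seeded reproducibility
  d1 <- withr::with_seed(5, constrained_draw(
    matrix(runif(10), ncol = 1), rep(1, 10), 0, flat, sp, ns_config()
  ))
  d2 <- withr::with_seed(5, constrained_draw(
    matrix(runif(10), ncol = 1), rep(1, 10), 0, flat, sp, ns_config()
  ))
  expect_identical(d1, d2)
})

test_that("evidence uncertainty tracks sqrt(H/n) and improves with n_live", {
  sp <- prior_spec(x = prior_uniform(-10, 10))
  ll <- function(th) dnorm(th[1], log = TRUE)
  lz50 <- vapply(1:12, function(s) {
    nested_sample(ll, sp, ns_config(n_live = 50, seed = s))$log_evidence
  }, numeric(1))
  r <- nested_sample(ll, sp, ns_config(n_live = 50, seed = 1))
  # empirical sd within a factor 2 of the reported sqrt(H/n)
  expect_lt(sd(lz50), 2 * r$log_evidence_sd)
  expect_gt(sd(lz50), r$log_evidence_sd / 2)
  lz200 <- vapply(1:12, function(s) {
    nested_sample(ll, sp, ns_config(n_live = 200, seed = s))$log_evidence
  }, numeric(1))
  # quadrupling n_live should roughly halve the spread (loose band)
  expect_lt(sd(lz200), sd(lz50))
})
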