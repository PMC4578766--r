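test_that("Jeffreys' scale maps the published bands", {
  expect_identical(jeffreys_category(1), "hardly worth mentioning")
  expect_identical(jeffreys_category(7), "strong")
  expect_identical(jeffreys_category(12), "very strong")
  expect_identical(jeffreys_category(c(0, 2, 6, 10)),
                   c("hardly worth mentioning", "has some substance",
                     "strong", "very strong"))
  expect_identical(jeffreys_category(-7), "strong (reversed)")
  expect_error(jeffreys_category(NaN), "NaN")
})

test_that("F statistic reproduces hand-built arithmetic", {
  # 8 points, sum (d - y_s)^2 = 2.0, sum (y_u - y_s)^2 = 1.0
  # => F = 1.0 / (2.0 / 7) = 3.5
  y_s <- rep(0, 8)
  d <- y_s + sqrt(2 / 8)        # residual-to-separated sum = 2.0
  y_u <- y_s + sqrt(1 / 8)      # unified-minus-separated sum = 1.0
  fs <- growthbayes:::.f_statistic(d, y_s, y_u)
  expect_equal(fs$num / fs$den, 3.5, tolerance = 1e-12)
  expect_identical(fs$df1, 1L)
  expect_identical(fs$df2, 1L)  # 8 points - 7 unified parameters
})

test_that("noise-free least-squares fits recover the generating parameters", {
  p <- base_params()
  cv <- simulate_growth_curve(p, sigma = 0, seed = 1)
  fit <- fit_growth_lsq(cv, seed = 2)
  expect_lt(fit$ssr, 1e-8)
  truth <- c(y0 = 3, mu_max = 0.11, h0 = 1, ymax = 9)
  expect_equal(fit$par, truth, tolerance = 1e-3)
})

test_that("unified SSR is never below separated SSR", {
  withr::with_seed(4, {
    for (i in 1:3) {
      ca <- simulate_growth_curve(base_params(), sigma = 0.15,
                                  seed = 100 + i)
      cb <- simulate_growth_curve(growth_params(4, 0.11 + 0.03 * i, 2, 8.5),
                                  sigma = 0.15, seed = 200 + i)
      sep <- fit_growth_lsq(ca, cb, "separated", seed = i)
      uni <- fit_growth_lsq(ca, cb, "unified", seed = i)
      expect_gte(uni$ssr, sep$ssr - 1e-6)
    }
  })
  # identical curves: the shared rate is true, SSRs agree
  cv <- simulate_growth_curve(base_params(), sigma = 0.1, seed = 9)
  sep <- fit_growth_lsq(cv, cv, "separated", seed = 1)
  uni <- fit_growth_lsq(cv, cv, "unified", seed = 1)
  expect_equal(uni$ssr, sep$ssr, tolerance = 1e-4)
})

test_that("F-test reports the documented degrees of freedom and verdicts", {
  ca <- simulate_growth_curve(base_params(), n_points = 16, sigma = 0.1,
                              seed = 21)
  cb <- simulate_growth_curve(base_params(0.22),
                              t_max = base_t_max(), n_points = 16,
                              sigma = 0.1, seed = 22)
  ft <- growth_f_test(ca, cb, seed = 1)
  expect_identical(ft$df1, 1L)
  expect_identical(ft$df2, 25L)  # 32 points - 7 unified parameters
  expect_true(ft$reject_null)    # large rate difference, low noise
  expect_identical(ft$reject_null, ft$p_value < 0.05)
  td <- tidy(ft)
  expect_named(td, c("statistic", "df1", "df2", "p.value", "reject_null",
                     "degenerate"))
  # identical fitted curves give F = 0, p = 1
  fs0 <- growthbayes:::.f_statistic(d = c(1, 2, 3, 4, 5, 6, 7, 8.5),
                                    y_s = 1:8, y_u = 1:8)
  expect_equal(fs0$num, 0)
  expect_equal(stats::pf(fs0$num / fs0$den, fs0$df1, fs0$df2,
                         lower.tail = FALSE), 1)
  # conventional variant uses N - 8 residual df
  ftc <- growth_f_test(ca, cb, seed = 1, conventional = TRUE)
  expect_identical(ftc$df2, 24L)
})

test_that("comparisons are seeded, additive and swap-invariant", {
  ca <- simulate_growth_curve(base_params(), sigma = 0.1, seed = 31)
  cb <- simulate_growth_curve(base_params(0.22), t_max = base_t_max(),
                              sigma = 0.1, seed = 32)
  cfg <- quick_config(seed = 41)
  cmp <- compare_growth_rates(ca, cb, config = cfg)
  # additivity is exact by construction from the shared lnZ values
  expect_equal(cmp$two_ln_b["H1", "H2"] + cmp$two_ln_b["H2", "H3"],
               cmp$two_ln_b["H1", "H3"], tolerance = 1e-12)
  expect_true(all(diag(cmp$two_ln_b) == 0))
  # reproducible given the seed
  cmp2 <- compare_growth_rates(ca, cb, config = cfg)
  expect_identical(cmp$evidence, cmp2$evidence)
  # a large true rate difference is detected and ranked H3 first
  expect_identical(cmp$verdict, "different")
  expect_gt(cmp$two_ln_b["H3", "H2"], 2)
  expect_gt(cmp$two_ln_b["H3", "H1"], 2)
  # swapping the curves leaves the evidence ranking intact
  cmp_swap <- compare_growth_rates(cb, ca, config = cfg)
  expect_identical(
    order(cmp$evidence$log_evidence),
    order(cmp_swap$evidence$log_evidence)
  )
  gl <- glance(cmp)
  expect_equal(gl$two_ln_b32, cmp$two_ln_b["H3", "H2"])
  expect_identical(gl$verdict, "different")
})

test_that("hypothesis subsets and informative rate priors are accepted", {
  ca <- simulate_growth_curve(base_params(), sigma = 0.1, seed = 51)
  cb <- simulate_growth_curve(base_params(), sigma = 0.1, seed = 52)
  mu_prior <- prior_gaussian(0.11, 0.01)
  cmp <- compare_growth_rates(ca, cb, hypotheses = c("H2", "H3"),
                              mu_prior = mu_prior,
                              config = quick_config(seed = 3))
  expect_setequal(cmp$evidence$hypothesis, c("H2", "H3"))
  expect_true(cmp$verdict %in% c("same", "different"))
  # the informative entry was truncated to finite data-scaled bounds
  expect_true(is.finite(cmp$mu_prior$shared$lower))
  expect_true(is.finite(cmp$mu_prior$shared$upper))
  expect_identical(cmp$mu_prior$a$dist, "gaussian")
})
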