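#' Simulation drivers for growth-rate detection studies
#'
#' Three experiment drivers mirror the package's core simulation designs:
#' a perturbation sweep of the Bayes factor as the difference in growth
#' rate between two curves increases, a detection-rate comparison between
#' the F-test and Bayes factors (with optional cluster-informed priors) over
#' noise levels, and an evidence sweep showing how informative priors rank
#' as a target curve's rate moves between two clusters. All drivers are
#' reproducible given `seed`, and every emitted row carries its generating
#' configuration.
#'
#' @name growth_experiments
NULL

# Second curve of a pair: same shape parameters as `base`, rate replaced.
.curve_at_rate <- function(base, mu, n_points, t_max, sigma, seed) {
  p <- growth_params(base$y0, mu, base$h0, base$ymax)
  simulate_growth_curve(p, n_points = n_points, t_max = t_max,
                        sigma = sigma, seed = seed)
}

# Analyse `n_members` simulated curves at rates spread over `range` and
# summarise their inferred growth rates as cluster members (mean, variance).
.build_cluster <- function(range, n_members, n_points, t_max, sigma,
                           base, config, seed) {
  rates <- seq(range[1L], range[2L], length.out = n_members)
  purrr::map_dfr(seq_along(rates), function(i) {
    cv <- .curve_at_rate(base, rates[i], n_points, t_max, sigma,
                         seed = .derive_seed(seed, i))
    cfg <- config
    cfg$seed <- .derive_seed(seed, 100L + i)
    fit <- growth_fit(cv, config = cfg)
    ps <- posterior_summary(fit$ns, "mu_max")
    tibble::tibble(mean = ps$mean, variance = ps$sd^2)
  })
}

#' Bayes-factor perturbation sweep over growth-rate differences
#'
#' Two curves are compared as the second curve's growth rate moves away
#' from the first's (fixed at `base_mu`). The first curve is generated once
#' per sweep; the second is regenerated with fresh noise for every
#' replicate. For each rate difference the mean and standard deviation of
#' \eqn{\ln B_{23}} (H2, equal rates, over H3, different rates) across
#' replicates is reported; increasingly negative values favour different
#' rates.
#'
#' @param delta_mu Vector of growth-rate differences (log10 units per
#'   hour).
#' @param sigma Noise sd, log10 units (default 0.1).
#' @param n_points Points per curve (default 32).
#' @param replicates Replicates per rate difference (default 10).
#' @param base_mu Growth rate of the fixed first curve (default 0.11).
#' @param base Shape parameters shared by both curves.
#' @param config An [ns_config()] for the per-hypothesis sampler runs.
#' @param seed Top-level seed; all curve noise and sampler seeds derive
#'   from it.
#' @return A tibble with one row per `delta_mu`: `mean_ln_b23`,
#'   `sd_ln_b23` plus the generating configuration columns.
#' @export
perturbation_sweep <- function(delta_mu, sigma = 0.1, n_points = 32,
                               replicates = 10, base_mu = 0.11,
                               base = growth_params(3, base_mu, 1, 9),
                               config = ns_config(), seed = 1) {
  stopifnot(length(delta_mu) >= 1L, replicates >= 1L)
  t_max <- time_to_fraction(base, 0.95)
  curve_a <- simulate_growth_curve(base, n_points = n_points, t_max = t_max,
                                   sigma = sigma, seed = .derive_seed(seed, 0L))
  purrr::map_dfr(seq_along(delta_mu), function(j) {
    dm <- delta_mu[j]
    lnb <- vapply(seq_len(replicates), function(r) {
      rep_seed <- .derive_seed(seed, j * 10000L + r)
      curve_b <- .curve_at_rate(base, base_mu + dm, n_points, t_max, sigma,
                                seed = rep_seed)
      cfg <- config
      cfg$seed <- .derive_seed(rep_seed, 1L)
      cmp <- compare_growth_rates(curve_a, curve_b,
                                  hypotheses = c("H2", "H3"), config = cfg)
      lnz <- stats::setNames(cmp$evidence$log_evidence,
                             cmp$evidence$hypothesis)
      lnz[["H2"]] - lnz[["H3"]]
    }, numeric(1))
    tibble::tibble(
      delta_mu = dm, mean_ln_b23 = mean(lnb), sd_ln_b23 = stats::sd(lnb),
      sigma = sigma, n_points = n_points, replicates = replicates,
      base_mu = base_mu, n_live = config$n_live, seed = seed
    )
  })
}

#' Detection-rate comparison: F-test vs Bayes factors across noise levels
#'
#' For each noise level, `replicates` curve pairs are generated (the first
#' curve fixed, the second regenerated with fresh noise) and every method
#' is asked whether the growth rates differ. The Bayes rule declares a
#' difference on substantial evidence, `2 ln B32 >= 2`; the F-test rejects
#' at the 0.05 level. Cluster-informed methods build Gaussian or Cauchy
#' priors from `cluster_size` previously analysed curves simulated at rates
#' near each curve's own rate (width `cluster_width`), combined via the law
#' of total variance; under H2 the shared rate uses the pooled members of
#' both clusters.
#'
#' @param sigma_levels Noise levels to scan (log10 units).
#' @param truth `"different"` (rates `base_mu` and `base_mu + delta_mu`)
#'   or `"equal"` (both `base_mu`).
#' @param delta_mu True rate difference when `truth = "different"`
#'   (default 0.11).
#' @param n_points Points per curve (default 32).
#' @param replicates Pairs per noise level (default 20).
#' @param methods Any of `"f_test"`, `"bayes_uniform"`, `"bayes_gaussian"`,
#'   `"bayes_cauchy"`.
#' @param cluster_size Curves per prior-knowledge cluster (default 4).
#' @param cluster_width Spread of the cluster members' rates (default
#'   0.02, i.e. rate +/- 0.01).
#' @param cluster_sigma Noise level of the previously analysed cluster
#'   curves (default 0.1).
#' @param base_mu Rate of the fixed first curve (default 0.11).
#' @param base Shape parameters shared by all curves.
#' @param config An [ns_config()].
#' @param seed Top-level seed.
#' @return A tibble with one row per noise level and method:
#'   `prop_correct`, `n_correct`, plus configuration columns.
#' @export
detection_comparison <- function(sigma_levels, truth = c("different", "equal"),
                                 delta_mu = 0.11, n_points = 32,
                                 replicates = 20,
                                 methods = c("f_test", "bayes_uniform",
                                             "bayes_gaussian", "bayes_cauchy"),
                                 cluster_size = 4, cluster_width = 0.02,
                                 cluster_sigma = 0.1, base_mu = 0.11,
                                 base = growth_params(3, base_mu, 1, 9),
                                 config = ns_config(), seed = 1) {
  truth <- match.arg(truth)
  methods <- match.arg(methods, several.ok = TRUE)
  mu_b <- if (truth == "different") base_mu + delta_mu else base_mu
  t_max <- time_to_fraction(base, 0.95)

  needs_cluster <- any(c("bayes_gaussian", "bayes_cauchy") %in% methods)
  cluster_a <- cluster_b <- pooled <- NULL
  if (needs_cluster) {
    cluster_a <- .build_cluster(
      base_mu + c(-0.5, 0.5) * cluster_width, cluster_size, n_points, t_max,
      cluster_sigma, base, config, seed = .derive_seed(seed, 900001L)
    )
    cluster_b <- if (mu_b == base_mu) cluster_a else .build_cluster(
      mu_b + c(-0.5, 0.5) * cluster_width, cluster_size, n_points, t_max,
      cluster_sigma, base, config, seed = .derive_seed(seed, 900002L)
    )
    pooled <- dplyr::bind_rows(cluster_a, cluster_b)
  }
  mu_prior_for <- function(kind) {
    list(a = cluster_prior(cluster_a, kind),
         b = cluster_prior(cluster_b, kind),
         shared = cluster_prior(pooled, kind))
  }

  grid <- tidyr::expand_grid(sigma = sigma_levels, rep = seq_len(replicates))
  results <- purrr::pmap_dfr(grid, function(sigma, rep) {
    pair_seed <- .derive_seed(seed, round(sigma * 1e5) * 1000L + rep)
    curve_a <- .curve_at_rate(base, base_mu, n_points, t_max, sigma,
                              seed = .derive_seed(pair_seed, 1L))
    curve_b <- .curve_at_rate(base, mu_b, n_points, t_max, sigma,
                              seed = .derive_seed(pair_seed, 2L))
    purrr::map_dfr(methods, function(m) {
      says_different <- if (m == "f_test") {
        ft <- growth_f_test(curve_a, curve_b, seed = .derive_seed(pair_seed, 3L))
        ft$reject_null
      } else {
        mp <- switch(m,
          bayes_uniform = NULL,
          bayes_gaussian = mu_prior_for("gaussian"),
          bayes_cauchy = mu_prior_for("cauchy")
        )
        cfg <- config
        cfg$seed <- .derive_seed(pair_seed, 4L + match(m, methods))
        cmp <- compare_growth_rates(curve_a, curve_b,
                                    hypotheses = c("H2", "H3"),
                                    mu_prior = mp, config = cfg)
        cmp$verdict == "different"
      }
      correct <- if (truth == "different") says_different else !says_different
      tibble::tibble(sigma = sigma, rep = rep, method = m, correct = correct)
    })
  })

  results |>
    dplyr::group_by(.data$sigma, .data$method) |>
    dplyr::summarise(n_correct = sum(.data$correct),
                     prop_correct = mean(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(truth = truth, delta_mu = delta_mu, n_points = n_points,
                  replicates = replicates, base_mu = base_mu,
                  n_live = config$n_live, seed = seed)
}

#' Evidence sweep: ranking priors as a curve moves between clusters
#'
#' Two clusters of simulated curves are analysed once to provide prior
#' knowledge (cluster A with rates over `cluster_a_range`, cluster B over
#' `cluster_b_range`). A target curve is then simulated at each rate in
#' `target_mu` and fitted under a uniform prior and under Gaussian/Cauchy
#' priors built from each requested cluster; the log-evidence of each fit
#' is recorded. Informative priors reward targets near their own cluster
#' and penalise distant ones, the Cauchy less harshly than the Gaussian,
#' while the uniform prior's evidence barely moves across the sweep.
#'
#' @param target_mu Vector of target growth rates to scan.
#' @param priors Subset of `c("uniform", "gaussian", "cauchy")`.
#' @param clusters Which clusters to use for informative priors, subset of
#'   `c("A", "B")`.
#' @param replicates Target curves per rate (default 10).
#' @param cluster_a_range,cluster_b_range Rate ranges of the two clusters
#'   (defaults 0.09-0.11 and 0.15-0.17).
#' @param cluster_size Curves per cluster (default 4).
#' @param sigma Noise sd for all simulated curves (default 0.1).
#' @param n_points Points per curve (default 32).
#' @param base Shape parameters shared by all curves.
#' @param config An [ns_config()].
#' @param seed Top-level seed.
#' @return A tibble with one row per (target rate, prior, cluster,
#'   replicate): `log_evidence` plus configuration columns. The `cluster`
#'   column is `NA` for the uniform prior.
#' @export
cluster_ranking_sweep <- function(target_mu,
                                  priors = c("uniform", "gaussian", "cauchy"),
                                  clusters = c("A", "B"),
                                  replicates = 10,
                                  cluster_a_range = c(0.09, 0.11),
                                  cluster_b_range = c(0.15, 0.17),
                                  cluster_size = 4, sigma = 0.1,
                                  n_points = 32,
                                  base = growth_params(3, 0.11, 1, 9),
                                  config = ns_config(), seed = 1) {
  priors <- match.arg(priors, several.ok = TRUE)
  clusters <- match.arg(clusters, several.ok = TRUE)
  t_max <- time_to_fraction(base, 0.95)
  members <- list(
    A = if ("A" %in% clusters) {
      .build_cluster(cluster_a_range, cluster_size, n_points, t_max, sigma,
                     base, config, seed = .derive_seed(seed, 910001L))
    },
    B = if ("B" %in% clusters) {
      .build_cluster(cluster_b_range, cluster_size, n_points, t_max, sigma,
                     base, config, seed = .derive_seed(seed, 910002L))
    }
  )

  cases <- dplyr::bind_rows(
    if ("uniform" %in% priors) tibble::tibble(prior = "uniform",
                                              cluster = NA_character_),
    tidyr::expand_grid(prior = setdiff(priors, "uniform"), cluster = clusters)
  )

  grid <- tidyr::expand_grid(mu = target_mu, rep = seq_len(replicates))
  purrr::pmap_dfr(grid, function(mu, rep) {
    curve_seed <- .derive_seed(seed, round(mu * 1e5) * 1000L + rep)
    target <- .curve_at_rate(base, mu, n_points, t_max, sigma,
                             seed = curve_seed)
    purrr::pmap_dfr(cases, function(prior, cluster) {
      mp <- if (prior == "uniform") NULL else {
        cluster_prior(members[[cluster]], prior)
      }
      cfg <- config
      cfg$seed <- .derive_seed(curve_seed,
                               match(prior, c("uniform", "gaussian", "cauchy")) *
                                 10L + match(cluster, c("A", "B"), nomatch = 0L))
      fit <- growth_fit(target, mu_prior = mp, config = cfg)
      tibble::tibble(
        target_mu = mu, prior = prior, cluster = cluster, rep = rep,
        log_evidence = fit$ns$log_evidence,
        sigma = sigma, n_points = n_points, n_live = config$n_live,
        seed = seed
      )
    })
  })
}
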