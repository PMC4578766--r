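#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL

# Builds the prior spec for a single-curve fit, applying user overrides.
.fit_spec <- function(curve, model, noise, sigma, priors, mu_prior) {
  spec <- default_priors(curve, model = model,
                         sigma = if (noise == "inferred") "inferred" else "fixed")
  entries <- unclass(spec)
  if (!is.null(mu_prior)) {
    stopifnot(inherits(mu_prior, "prior_entry"))
    entries$mu_max <- mu_prior
  }
  if (!is.null(priors)) {
    stopifnot(is.list(priors))
    for (nm in names(priors)) {
      if (!nm %in% names(entries)) {
        stop(sprintf("Unknown prior entry `%s`.", nm), call. = FALSE)
      }
      stopifnot(inherits(priors[[nm]], "prior_entry"))
      entries[[nm]] <- priors[[nm]]
    }
  }
  do.call(prior_spec, entries)
}

# theta (in spec order) -> full 4-vector (y0, mu_max, h0, ymax), filling in
# the fixed values of restricted model variants.
.theta_expander <- function(spec_names, model) {
  free <- model_free_params(model)
  pos <- match(free, spec_names)
  h0_fixed <- !"h0" %in% free
  ymax_fixed <- !"ymax" %in% free
  i_y0 <- match("y0", spec_names)
  i_mu <- match("mu_max", spec_names)
  i_h0 <- match("h0", spec_names)
  i_ym <- match("ymax", spec_names)
  function(theta) {
    c(theta[i_y0], theta[i_mu],
      if (h0_fixed) 0 else theta[i_h0],
      if (ymax_fixed) Inf else theta[i_ym])
  }
}

#' Fit the growth model to a single curve by nested sampling
#'
#' Bayesian inference for one growth curve: runs nested sampling on the
#' curve's likelihood under the chosen model variant, returning the model
#' evidence (marginal likelihood) together with weighted posterior samples.
#' The noise level may be inferred under a Jeffreys prior (recommended) or
#' prescribed. All parameters are reported on the log10 scale.
#'
#' @param curve A [growth_curve()].
#' @param model Growth-model variant (see [model_free_params()]).
#' @param noise `"inferred"` (default) or `"fixed"`.
#' @param sigma Noise sd (log10), required when `noise = "fixed"`.
#' @param priors Optional named list of `prior_entry` overrides.
#' @param mu_prior Optional informative `prior_entry` for `mu_max`, e.g.
#'   from [cluster_prior()]. Unbounded informative entries are truncated to
#'   the data-scaled default bounds.
#' @param tail_sd Gaussian-tail sd for censored points, see
#'   [loglik_censored_point()].
#' @param config An [ns_config()].
#' @return A `growth_fit` object; see [tidy()] and [glance()] methods.
#' @examples
#' curve <- simulate_growth_curve(seed = 1)
#' fit <- growth_fit(curve, config = ns_config(n_live = 50, seed = 1))
#' tidy(fit)
#' @export
growth_fit <- function(curve, model = "baranyi",
                       noise = c("inferred", "fixed"), sigma = NULL,
                       priors = NULL, mu_prior = NULL, tail_sd = 0.05,
                       config = ns_config()) {
  stopifnot(inherits(curve, "growth_curve"))
  noise <- match.arg(noise)
  if (noise == "fixed" &&
      (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)) {
    stop("`noise = \"fixed\"` requires a positive `sigma`.", call. = FALSE)
  }
  if (!is.null(mu_prior) && mu_prior$dist %in% c("gaussian", "cauchy") &&
      (!is.finite(mu_prior$lower) || !is.finite(mu_prior$upper))) {
    db <- default_priors(curve, model = model)$mu_max
    mu_prior$lower <- max(mu_prior$lower, db$lower)
    mu_prior$upper <- min(mu_prior$upper, db$upper)
  }
  spec <- .fit_spec(curve, model, noise, sigma, priors, mu_prior)
  spec_names <- names(spec)
  expand <- .theta_expander(spec_names, model)
  ll_curve <- .compile_curve_loglik(curve, tail_sd)
  i_sigma <- match("sigma", spec_names)
  has_joint <- all(c("y0", "ymax") %in% spec_names)
  i_y0 <- match("y0", spec_names)
  i_ym <- match("ymax", spec_names)
  sigma_fixed <- sigma
  loglik <- function(theta) {
    if (has_joint && theta[i_ym] <= theta[i_y0]) return(-Inf)
    s <- if (is.na(i_sigma)) sigma_fixed else theta[i_sigma]
    ll_curve(expand(theta), s)
  }
  ns <- nested_sample(loglik, spec, config)
  structure(
    list(ns = ns, curve = curve, model = model, noise = noise,
         sigma_fixed = if (noise == "fixed") sigma else NULL,
         spec = spec, tail_sd = tail_sd, config = config),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Bayesian growth-curve fit (%s model, %s noise)\n",
              x$model, x$noise))
  print(x$ns)
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' Tidy a Bayesian growth-curve fit
#'
#' One row per parameter with posterior mean and standard deviation
#' (log10 reporting scale), plus a derived `lag_time` row in hours.
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  ps <- posterior_summary(x$ns)
  out <- tibble::tibble(term = ps$parameter, estimate = ps$mean,
                        std.error = ps$sd)
  if (all(c("h0", "mu_max") %in% out$term)) {
    draws <- staircase_sample(x$ns, 2000, seed = 1L)
    lag <- draws$h0 / (draws$mu_max * LN10)
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "lag_time", estimate = mean(lag), std.error = stats::sd(lag)
    ))
  }
  out
}

#' Glance at a Bayesian growth-curve fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `log_evidence`, `log_evidence_sd`,
#'   `information`, `n_iterations`, `converged`, `n_obs`.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    log_evidence = x$ns$log_evidence,
    log_evidence_sd = x$ns$log_evidence_sd,
    information = x$ns$information,
    n_iterations = x$ns$n_iterations,
    converged = x$ns$converged,
    n_obs = nrow(x$curve)
  )
}
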