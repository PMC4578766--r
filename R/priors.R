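#' Prior distributions for growth-model parameters
#'
#' Per-parameter prior entries: a flat uniform, a truncated Gaussian
#' (informative), a truncated Cauchy (weakly informative, heavier tails),
#' and the scale-invariant Jeffreys prior (density proportional to
#' \eqn{1/\sigma}) for the noise level. All densities are normalized over
#' their truncation interval.
#'
#' @param lower,upper Support bounds, `lower < upper`; Jeffreys bounds must
#'   be strictly positive.
#' @param mean,sd Location and spread of the Gaussian entry (`sd > 0`).
#' @param location,scale Location and scale of the Cauchy entry
#'   (`scale > 0`).
#' @return A `prior_entry` object.
#' @name prior_entries
NULL

.new_entry <- function(dist, ...) {
  e <- c(list(dist = dist), list(...))
  if (!is.numeric(e$lower) || !is.numeric(e$upper) || e$lower >= e$upper) {
    stop("Prior bounds must satisfy lower < upper.", call. = FALSE)
  }
  structure(e, class = "prior_entry")
}

#' @rdname prior_entries
#' @export
prior_uniform <- function(lower, upper) {
  .new_entry("uniform", lower = lower, upper = upper)
}

#' @rdname prior_entries
#' @export
prior_gaussian <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive.", call. = FALSE)
  .new_entry("gaussian", mean = mean, sd = sd, lower = lower, upper = upper)
}

#' @rdname prior_entries
#' @export
prior_cauchy <- function(location, scale, lower = -Inf, upper = Inf) {
  if (!is.numeric(scale) || scale <= 0) {
    stop("`scale` must be positive.", call. = FALSE)
  }
  .new_entry("cauchy", location = location, scale = scale,
             lower = lower, upper = upper)
}

#' @rdname prior_entries
#' @export
prior_jeffreys <- function(lower, upper) {
  if (lower <= 0) {
    stop("Jeffreys prior bounds must be strictly positive.", call. = FALSE)
  }
  .new_entry("jeffreys", lower = lower, upper = upper)
}

#' @export
print.prior_entry <- function(x, ...) {
  fields <- setdiff(names(x), "dist")
  cat(sprintf("%s(%s)\n", x$dist,
              paste(sprintf("%s = %g", fields,
                            unlist(x[fields])), collapse = ", ")))
  invisible(x)
}

#' Assemble a named prior specification
#'
#' @param ... Named `prior_entry` objects, e.g. `y0 = prior_uniform(0, 9)`.
#'   Conventional names are `y0`, `mu_max`, `h0`, `ymax` and `sigma`.
#' @return A `prior_spec` object (named list of entries). When both `y0`
#'   and `ymax` are present the joint support is additionally restricted to
#'   `ymax > y0` (zero prior mass elsewhere).
#' @export
prior_spec <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L || is.null(names(entries)) ||
      any(!nzchar(names(entries)))) {
    stop("All prior entries must be named.", call. = FALSE)
  }
  ok <- vapply(entries, inherits, logical(1), "prior_entry")
  if (!all(ok)) {
    stop("All arguments must be `prior_entry` objects.", call. = FALSE)
  }
  structure(entries, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-7s ", nm))
    print(x[[nm]])
  }
  invisible(x)
}

#' Data-scaled default priors for a growth curve
#'
#' Uniform bounds chosen to scale with the observed data (range
#' `r = max(logc) - min(logc)`, floored at 1 for degenerate curves, and
#' time span `T`): `y0` in `[dmin - r/2, dmax]`, `ymax` in
#' `[dmin, dmax + r/2]`, `mu_max` in `(1e-6, 10 r / T]`, `h0` in
#' `[0, mu_upper * t_max]`, and a Jeffreys prior on `sigma` over
#' `[1e-3, r]` when the noise level is inferred.
#'
#' @param curve A [growth_curve()].
#' @param model Growth-model variant; restricted variants drop the
#'   corresponding entries (see [model_free_params()]).
#' @param sigma `"inferred"` to include the Jeffreys entry for the noise
#'   level, `"fixed"` to omit it.
#' @return A [prior_spec()].
#' @export
default_priors <- function(curve, model = "baranyi",
                           sigma = c("inferred", "fixed")) {
  stopifnot(inherits(curve, "growth_curve"))
  sigma <- match.arg(sigma)
  if (nrow(curve) < 2L) {
    stop("Need at least 2 observations.", call. = FALSE)
  }
  d_min <- min(curve$logc)
  d_max <- max(curve$logc)
  t_span <- max(curve$time) - min(curve$time)
  if (t_span <= 0) stop("Zero time span.", call. = FALSE)
  r <- max(d_max - d_min, 1)
  mu_upper <- 10 * r / t_span
  entries <- list(
    y0     = prior_uniform(d_min - r / 2, d_max),
    mu_max = prior_uniform(1e-6, mu_upper),
    h0     = prior_uniform(0, mu_upper * max(curve$time)),
    ymax   = prior_uniform(d_min, d_max + r / 2)
  )
  entries <- entries[model_free_params(model)]
  if (sigma == "inferred") entries$sigma <- prior_jeffreys(1e-3, r)
  do.call(prior_spec, entries)
}

#' Cluster-informed prior for the growth rate
#'
#' Builds an informative Gaussian or weakly informative Cauchy prior for
#' `mu_max` from the inferred growth rates of `N` previously analysed
#' curves in a cluster. The cluster mean is the mean of the member means
#' and the cluster variance follows the law of total variance:
#' \deqn{\sigma^2_{cluster} = \overline{\mu_i^2} - \bar{\mu_i}^2
#'   + \overline{\sigma_i^2},}
#' i.e. the between-member variance of the means plus the mean
#' within-member variance. The square root is used as the Gaussian sd and
#' as the Cauchy scale.
#'
#' @param members A data frame with columns `mean` and `variance` (one row
#'   per previously analysed curve, on the log10 scale).
#' @param kind `"gaussian"` (informative) or `"cauchy"` (weakly
#'   informative).
#' @param lower,upper Truncation bounds for the resulting entry; defaults
#'   to unbounded. In practice pass the data-scaled `mu_max` bounds.
#' @return A `prior_entry` for `mu_max`.
#' @examples
#' cl <- data.frame(mean = c(0.1, 0.2), variance = c(1e-4, 4e-4))
#' cluster_prior(cl)  # location 0.15, variance 0.00275
#' @export
cluster_prior <- function(members, kind = c("gaussian", "cauchy"),
                          lower = -Inf, upper = Inf) {
  kind <- match.arg(kind)
  if (!is.data.frame(members) ||
      !all(c("mean", "variance") %in% names(members))) {
    stop("`members` must be a data frame with columns `mean` and `variance`.",
         call. = FALSE)
  }
  if (nrow(members) < 1L) {
    stop("`members` must have at least one row.", call. = FALSE)
  }
  if (any(members$variance < 0)) {
    stop("Member variances must be non-negative.", call. = FALSE)
  }
  mu_cluster <- mean(members$mean)
  var_cluster <- mean(members$mean^2) - mu_cluster^2 + mean(members$variance)
  sd_cluster <- sqrt(var_cluster)
  if (sd_cluster <= 0) {
    stop("Cluster variance is zero; cannot build an informative prior.",
         call. = FALSE)
  }
  if (kind == "gaussian") {
    prior_gaussian(mu_cluster, sd_cluster, lower, upper)
  } else {
    prior_cauchy(mu_cluster, sd_cluster, lower, upper)
  }
}

# ---- transforms and densities ------------------------------------------

.entry_transform <- function(entry, u) {
  switch(entry$dist,
    uniform = entry$lower + u * (entry$upper - entry$lower),
    jeffreys = entry$lower * (entry$upper / entry$lower)^u,
    gaussian = {
      plo <- stats::pnorm(entry$lower, entry$mean, entry$sd)
      phi <- stats::pnorm(entry$upper, entry$mean, entry$sd)
      stats::qnorm(plo + u * (phi - plo), entry$mean, entry$sd)
    },
    cauchy = {
      plo <- stats::pcauchy(entry$lower, entry$location, entry$scale)
      phi <- stats::pcauchy(entry$upper, entry$location, entry$scale)
      stats::qcauchy(plo + u * (phi - plo), entry$location, entry$scale)
    }
  )
}

.entry_cdf <- function(entry, x) {
  switch(entry$dist,
    uniform = (x - entry$lower) / (entry$upper - entry$lower),
    jeffreys = log(x / entry$lower) / log(entry$upper / entry$lower),
    gaussian = {
      plo <- stats::pnorm(entry$lower, entry$mean, entry$sd)
      phi <- stats::pnorm(entry$upper, entry$mean, entry$sd)
      (stats::pnorm(x, entry$mean, entry$sd) - plo) / (phi - plo)
    },
    cauchy = {
      plo <- stats::pcauchy(entry$lower, entry$location, entry$scale)
      phi <- stats::pcauchy(entry$upper, entry$location, entry$scale)
      (stats::pcauchy(x, entry$location, entry$scale) - plo) / (phi - plo)
    }
  )
}

.entry_logdens <- function(entry, x) {
  out <- rep(-Inf, length(x))
  inside <- x >= entry$lower & x <= entry$upper
  if (!any(inside)) return(out)
  xi <- x[inside]
  out[inside] <- switch(entry$dist,
    uniform = rep(-log(entry$upper - entry$lower), length(xi)),
    jeffreys = -log(xi) - log(log(entry$upper / entry$lower)),
    gaussian = {
      z <- stats::pnorm(entry$upper, entry$mean, entry$sd) -
        stats::pnorm(entry$lower, entry$mean, entry$sd)
      stats::dnorm(xi, entry$mean, entry$sd, log = TRUE) - log(z)
    },
    cauchy = {
      z <- stats::pcauchy(entry$upper, entry$location, entry$scale) -
        stats::pcauchy(entry$lower, entry$location, entry$scale)
      stats::dcauchy(xi, entry$location, entry$scale, log = TRUE) - log(z)
    }
  )
  out
}

#' Map unit-hypercube coordinates onto the prior
#'
#' Componentwise inverse-CDF transform: a point uniform on `[0,1]^d` is
#' mapped to a draw from the prior. This is the representation the nested
#' sampler works in.
#'
#' @param u Numeric vector in `[0,1]^d`, one component per entry of `spec`
#'   (in the order of `names(spec)`).
#' @param spec A [prior_spec()].
#' @return Named numeric parameter vector.
#' @export
prior_transform <- function(u, spec) {
  stopifnot(inherits(spec, "prior_spec"))
  if (length(u) != length(spec)) {
    stop("`u` must have one component per prior entry.", call. = FALSE)
  }
  if (any(u < 0 | u > 1) || anyNA(u)) {
    stop("`u` must lie in the unit hypercube.", call. = FALSE)
  }
  out <- vapply(seq_along(spec),
                function(i) .entry_transform(spec[[i]], u[i]), numeric(1))
  names(out) <- names(spec)
  out
}

#' Log prior density of a parameter vector
#'
#' Sum of per-entry log densities (each normalized over its truncation
#' interval), with the joint constraint `ymax > y0` enforced by returning
#' `-Inf` (zero prior mass) when violated. Points outside any entry's
#' support also give `-Inf` rather than an error.
#'
#' @param params Named numeric vector matching `names(spec)`.
#' @param spec A [prior_spec()].
#' @return Log density (a single number, possibly `-Inf`).
#' @export
log_prior_density <- function(params, spec) {
  stopifnot(inherits(spec, "prior_spec"))
  if (is.list(params)) params <- unlist(params[names(spec)])
  if (is.null(names(params))) {
    names(params) <- names(spec)
  }
  if (!all(names(spec) %in% names(params))) {
    stop("`params` must carry every prior entry's name.", call. = FALSE)
  }
  if (all(c("y0", "ymax") %in% names(params)) &&
      params[["ymax"]] <= params[["y0"]]) {
    return(-Inf)
  }
  sum(vapply(names(spec),
             function(nm) .entry_logdens(spec[[nm]], params[[nm]]),
             numeric(1)))
}

# Compile a spec into fast closures for sampler loops: transform (vector in
# [0,1]^d -> unnamed parameter vector) grouped by distribution type.
.compile_transform <- function(spec) {
  d <- length(spec)
  dists <- vapply(spec, `[[`, character(1), "dist")
  lower <- vapply(spec, `[[`, numeric(1), "lower")
  upper <- vapply(spec, `[[`, numeric(1), "upper")
  iu <- which(dists == "uniform")
  ij <- which(dists == "jeffreys")
  ig <- which(dists == "gaussian")
  ic <- which(dists == "cauchy")
  width <- upper - lower
  lratio <- rep(NA_real_, d)
  if (length(ij)) lratio[ij] <- log(upper[ij] / lower[ij])
  gm <- vapply(spec, function(e) if (e$dist == "gaussian") e$mean else NA_real_,
               numeric(1))
  gs <- vapply(spec, function(e) if (e$dist == "gaussian") e$sd else NA_real_,
               numeric(1))
  cm <- vapply(spec,
               function(e) if (e$dist == "cauchy") e$location else NA_real_,
               numeric(1))
  cs <- vapply(spec,
               function(e) if (e$dist == "cauchy") e$scale else NA_real_,
               numeric(1))
  gplo <- gphi <- cplo <- cphi <- rep(NA_real_, d)
  if (length(ig)) {
    gplo[ig] <- stats::pnorm(lower[ig], gm[ig], gs[ig])
    gphi[ig] <- stats::pnorm(upper[ig], gm[ig], gs[ig])
  }
  if (length(ic)) {
    cplo[ic] <- stats::pcauchy(lower[ic], cm[ic], cs[ic])
    cphi[ic] <- stats::pcauchy(upper[ic], cm[ic], cs[ic])
  }
  function(u) {
    x <- numeric(d)
    if (length(iu)) x[iu] <- lower[iu] + u[iu] * width[iu]
    if (length(ij)) x[ij] <- lower[ij] * exp(u[ij] * lratio[ij])
    if (length(ig)) {
      x[ig] <- stats::qnorm(gplo[ig] + u[ig] * (gphi[ig] - gplo[ig]),
                            gm[ig], gs[ig])
    }
    if (length(ic)) {
      x[ic] <- stats::qcauchy(cplo[ic] + u[ic] * (cphi[ic] - cplo[ic]),
                              cm[ic], cs[ic])
    }
    x
  }
}
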