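#' Nested-sampling configuration
#'
#' Control parameters for the sampler: size of the active set (`n_live`),
#' length of the likelihood-constrained random walk used to replace the
#' discarded point (`max_mcmc_steps`), the termination tolerance (the run
#' stops once the largest possible remaining contribution,
#' `max(L_live) * X_k`, falls below `termination_tolerance` times the
#' accumulated evidence), a hard iteration cap, and a seed.
#'
#' @param n_live Number of live points (default 100, minimum 2).
#' @param max_mcmc_steps Steps of the constrained walk per replacement
#'   (default 20).
#' @param termination_tolerance Relative evidence tolerance in (0, 1),
#'   default `1e-6`.
#' @param max_iterations Safety cap on iterations (default `1e5`).
#' @param seed Optional integer seed; given a seed, runs are reproducible
#'   bit-for-bit and the caller's RNG state is left untouched.
#' @return An `ns_config` list.
#' @export
ns_config <- function(n_live = 100, max_mcmc_steps = 20,
                      termination_tolerance = 1e-6,
                      max_iterations = 1e5, seed = NULL) {
  if (n_live < 2) stop("`n_live` must be at least 2.", call. = FALSE)
  if (max_mcmc_steps < 1) {
    stop("`max_mcmc_steps` must be positive.", call. = FALSE)
  }
  if (termination_tolerance <= 0 || termination_tolerance >= 1) {
    stop("`termination_tolerance` must lie in (0, 1).", call. = FALSE)
  }
  structure(
    list(n_live = as.integer(n_live),
         max_mcmc_steps = as.integer(max_mcmc_steps),
         termination_tolerance = termination_tolerance,
         max_iterations = as.integer(max_iterations),
         seed = seed),
    class = "ns_config"
  )
}

.logsumexp <- function(a, b) {
  m <- max(a, b)
  if (m == -Inf) return(-Inf)
  m + log(exp(a - m) + exp(b - m))
}

.logsumexp_vec <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Reflect a proposal back into [0,1]^d.
.reflect <- function(u) {
  u <- abs(u) %% 2
  ifelse(u > 1, 2 - u, u)
}

#' Likelihood-constrained draw from the prior
#'
#' Generates a new point with log-likelihood strictly above `l_star`,
#' approximately distributed as the prior restricted to that region. The
#' draw is a Metropolis random walk in the unit hypercube (where the prior
#' is uniform by construction of the inverse-CDF transform), started from a
#' uniformly chosen surviving live point; proposals with likelihood at or
#' below `l_star` are rejected. If no proposal is ever accepted the start
#' point is returned with a warning.
#'
#' @param live_u Matrix of live-point cube coordinates (rows are points).
#' @param live_l Vector of live-point log-likelihoods.
#' @param l_star Likelihood floor; at least one live point must exceed it.
#' @param loglik Function taking a parameter vector, returning the
#'   log-likelihood.
#' @param spec A [prior_spec()] defining the cube-to-parameter transform.
#' @param config An [ns_config()]; `max_mcmc_steps` and nothing else is
#'   consulted.
#' @param step Walk step size (sd of the per-dimension Gaussian proposal in
#'   cube coordinates).
#' @return List with `u` (cube coordinates), `theta` (parameters), `loglik`
#'   and `accept_rate`.
#' @export
constrained_draw <- function(live_u, live_l, l_star, loglik, spec,
                             config = ns_config(), step = 0.1) {
  stopifnot(inherits(spec, "prior_spec"))
  transform <- .compile_transform(spec)
  ok <- which(live_l > l_star)
  if (length(ok) == 0L) {
    stop("No live point exceeds the likelihood floor.", call. = FALSE)
  }
  start <- ok[sample.int(length(ok), 1L)]
  .walk(live_u[start, , drop = TRUE], live_l[start], l_star, loglik,
        transform, config$max_mcmc_steps, step, warn = TRUE)
}

# `step` may be a scalar or a per-dimension vector of proposal sds in
# cube coordinates.
.walk <- function(u, lu, l_star, loglik, transform, n_steps, step,
                  warn = FALSE) {
  d <- length(u)
  n_acc <- 0L
  eps <- matrix(stats::rnorm(n_steps * d), nrow = n_steps)
  eps <- eps * rep(step, length.out = d)[col(eps)]
  for (s in seq_len(n_steps)) {
    up <- abs(u + eps[s, ]) %% 2
    over <- up > 1
    if (any(over)) up[over] <- 2 - up[over]
    lp <- loglik(transform(up))
    if (lp > l_star) {
      u <- up
      lu <- lp
      n_acc <- n_acc + 1L
    }
  }
  if (warn && n_acc == 0L) {
    warning("Constrained walk accepted no proposal; returning start point.",
            call. = FALSE)
  }
  list(u = u, theta = transform(u), loglik = lu,
       accept_rate = n_acc / n_steps)
}

#' Run nested sampling
#'
#' Skilling-style nested sampling for an arbitrary (log-likelihood, prior)
#' pair. An active set of `n_live` points drawn from the prior is evolved
#' by repeatedly discarding the point of lowest likelihood \eqn{L^*} and
#' replacing it with a likelihood-constrained prior draw; the evidence
#' \eqn{Z = \int L \pi \, dp} is accumulated as \eqn{\sum_k h_k L_k} with
#' deterministic shrinkage \eqn{X_k = e^{-k/n}} and widths
#' \eqn{h_k = X_{k-1} - X_k}. At termination the remaining live points are
#' added with equal widths `X_final / n_live`. All accumulation is in log
#' space.
#'
#' @param loglik Function of an unnamed parameter vector (ordered as
#'   `names(spec)`) returning a log-likelihood; may return `-Inf`.
#' @param spec A [prior_spec()].
#' @param config An [ns_config()].
#' @return An `ns_result` with elements `log_evidence`,
#'   `log_evidence_sd` (\eqn{\sqrt{H/n}}), `information` (H, in nats),
#'   `samples` (a tibble of parameters, `log_lik`, `log_width` and
#'   normalized `weight`), `n_iterations`, and `converged` (`FALSE` when
#'   the iteration cap ended the run).
#' @examples
#' sp <- prior_spec(x = prior_uniform(-10, 10))
#' r <- nested_sample(function(p) dnorm(p[1], log = TRUE), sp,
#'                    ns_config(n_live = 50, seed = 1))
#' r$log_evidence  # close to ln(1/20)
#' @export
nested_sample <- function(loglik, spec, config = ns_config()) {
  stopifnot(inherits(spec, "prior_spec"), inherits(config, "ns_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  n <- config$n_live
  d <- length(spec)
  transform <- .compile_transform(spec)

  U <- matrix(stats::runif(n * d), nrow = n)
  L <- numeric(n)
  TH <- matrix(0, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    TH[i, ] <- transform(U[i, ])
    L[i] <- loglik(TH[i, ])
  }
  if (all(!is.finite(L))) {
    stop("All initial prior draws have zero likelihood; check the prior ",
         "support and likelihood.", call. = FALSE)
  }

  cap <- 4096L
  dead_theta <- matrix(0, nrow = cap, ncol = d)
  dead_l <- numeric(cap)
  dead_logw <- numeric(cap)

  log_z <- -Inf
  log_x_prev <- 0
  scale <- 0.5
  k <- 0L
  converged <- FALSE
  tol_log <- log(config$termination_tolerance)

  repeat {
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      dead_theta <- rbind(dead_theta, matrix(0, nrow = cap / 2L, ncol = d))
      dead_l <- c(dead_l, numeric(cap / 2L))
      dead_logw <- c(dead_logw, numeric(cap / 2L))
    }
    i_min <- which.min(L)
    l_star <- L[i_min]
    log_x <- -k / n
    # h_k = X_{k-1} - X_k, in log space
    log_h <- log_x_prev + log1p(-exp(log_x - log_x_prev))
    log_x_prev <- log_x
    dead_theta[k, ] <- TH[i_min, ]
    dead_l[k] <- l_star
    dead_logw[k] <- log_h
    if (is.finite(l_star)) log_z <- .logsumexp(log_z, log_h + l_star)

    # replace the discarded point: per-dimension proposal sds follow the
    # live set's spread in cube coordinates, so directions the data leave
    # wide keep mixing while constrained ones take short steps
    col_m <- colMeans(U)
    col_sd <- sqrt(pmax(colMeans(U * U) - col_m^2, 1e-12))
    step <- pmin(pmax(scale * col_sd, 1e-5), 1)
    ok <- which(L > l_star)
    if (length(ok) == 0L) ok <- seq_len(n)[-i_min]
    start <- ok[sample.int(length(ok), 1L)]
    res <- .walk(U[start, ], L[start], l_star, loglik, transform,
                 config$max_mcmc_steps, step)
    U[i_min, ] <- res$u
    TH[i_min, ] <- res$theta
    L[i_min] <- res$loglik

    # adapt the global scale between iterations (frozen within a walk),
    # targeting acceptance in [0.2, 0.6]
    if (res$accept_rate < 0.2) {
      scale <- max(scale * 0.7, 0.01)
    } else if (res$accept_rate > 0.6) {
      scale <- min(scale * 1.4, 5)
    }

    l_max <- max(L)
    if (is.finite(log_z) && is.finite(l_max) &&
        l_max + log_x < tol_log + log_z) {
      converged <- TRUE
      break
    }
    if (k >= config$max_iterations) break
  }

  # remaining live points, each with width X_final / n
  log_x_final <- -k / n
  log_w_live <- log_x_final - log(n)
  ord <- order(L)
  live_theta <- TH[ord, , drop = FALSE]
  live_l <- L[ord]
  fin <- is.finite(live_l)
  if (any(fin)) {
    log_z <- .logsumexp(log_z, log_w_live + .logsumexp_vec(live_l[fin]))
  }

  all_theta <- rbind(dead_theta[seq_len(k), , drop = FALSE], live_theta)
  all_l <- c(dead_l[seq_len(k)], live_l)
  all_logw <- c(dead_logw[seq_len(k)], rep(log_w_live, n))

  log_wt <- all_logw + all_l - log_z
  log_wt[!is.finite(all_l)] <- -Inf
  weight <- exp(log_wt)
  weight <- weight / sum(weight)

  info_terms <- weight * (all_l - log_z)
  information <- sum(info_terms[weight > 0])
  sd_log_z <- sqrt(max(information, 0) / n)

  samples <- tibble::as_tibble(as.data.frame(all_theta))
  names(samples) <- names(spec)
  samples$log_lik <- all_l
  samples$log_width <- all_logw
  samples$weight <- weight

  structure(
    list(log_evidence = log_z,
         log_evidence_sd = sd_log_z,
         information = information,
         samples = samples,
         n_iterations = k,
         n_live = n,
         converged = converged,
         parameters = names(spec)),
    class = "ns_result"
  )
}

#' @export
print.ns_result <- function(x, ...) {
  cat(sprintf(
    "Nested sampling: ln Z = %.4f +/- %.4f (H = %.2f nats, %d iterations%s)\n",
    x$log_evidence, x$log_evidence_sd, x$information, x$n_iterations,
    if (x$converged) "" else "; iteration cap reached"
  ))
  invisible(x)
}

#' Posterior mean and standard deviation from a nested-sampling run
#'
#' Weighted moments over the recorded samples: `mean = sum(w_k p_k)` and
#' `sd = sqrt(sum(w_k p_k^2) - mean^2)` (clipped at zero against round-off).
#'
#' @param result An `ns_result` from [nested_sample()].
#' @param parameters Optional character vector restricting the summary.
#' @return A tibble with columns `parameter`, `mean`, `sd`.
#' @export
posterior_summary <- function(result, parameters = NULL) {
  stopifnot(inherits(result, "ns_result"))
  if (nrow(result$samples) < 1L) {
    stop("Empty nested-sampling result.", call. = FALSE)
  }
  pars <- parameters %||% result$parameters
  w <- result$samples$weight
  purrr::map_dfr(pars, function(nm) {
    p <- result$samples[[nm]]
    m <- sum(w * p)
    v <- max(sum(w * p^2) - m^2, 0)
    tibble::tibble(parameter = nm, mean = m, sd = sqrt(v))
  })
}

#' Equally weighted posterior draws by staircase resampling
#'
#' Resamples the weighted nested-sampling outputs with replacement,
#' proportionally to their posterior weights, giving equally weighted
#' posterior draws (the nested-sampling analogue of MCMC output).
#'
#' @param result An `ns_result`.
#' @param count Number of draws, positive.
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return A tibble of `count` parameter rows.
#' @export
staircase_sample <- function(result, count, seed = NULL) {
  stopifnot(inherits(result, "ns_result"))
  if (!is.numeric(count) || length(count) != 1L || count < 1) {
    stop("`count` must be a positive integer.", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  idx <- sample.int(nrow(result$samples), size = count, replace = TRUE,
                    prob = result$samples$weight)
  result$samples[idx, result$parameters, drop = FALSE]
}
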