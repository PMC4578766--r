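#' Gaussian log-likelihood of a growth curve
#'
#' The log-likelihood of `N` independent observations with Gaussian errors
#' of common standard deviation `sigma` on the log10 scale:
#' \deqn{\log L = -\sum_i \log(\sigma \sqrt{2\pi})
#'   - \tfrac{1}{2} \sum_i (d_i - y_i)^2 / \sigma^2.}
#' All points of `curve` are treated as uncensored; callers that handle
#' detection-limit observations should use [loglik_curve()], which routes
#' censored points through [loglik_censored_point()].
#'
#' @param curve A [growth_curve()].
#' @param params A [growth_params()] (any scale; predictions are compared
#'   on log10).
#' @param sigma Noise standard deviation on the log10 scale, positive.
#' @return Log-likelihood (a single number).
#' @export
loglik_gaussian <- function(curve, params, sigma) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  p <- convert_scale(params, to = "log10")
  pred <- growth_predict(curve$time, p)
  .ll_gauss(curve$logc, pred, sigma)
}

.ll_gauss <- function(d, y, sigma) {
  if (length(d) != length(y)) {
    stop("Observed and predicted vectors differ in length.", call. = FALSE)
  }
  n <- length(d)
  -n * log(sigma * sqrt(2 * pi)) - sum((d - y)^2) / (2 * sigma^2)
}

#' Log-likelihood of a below-detection observation
#'
#' A censored point carries no information about where the concentration
#' lies below the detection limit, so its likelihood is uniform on
#' `[0, threshold]` (density `1/threshold` on the log10 scale) whenever the
#' model prediction is at or below the threshold. Above the threshold a
#' small Gaussian tail is attached so the log-likelihood stays finite and
#' continuous rather than dropping to \eqn{-\infty}:
#' \deqn{\log(1/T) - (y - T)^2 / (2 \tau^2), \quad y > T.}
#'
#' @param predicted Model prediction(s), log10 scale.
#' @param threshold Detection threshold, log10 scale, positive.
#' @param tail_sd Standard deviation \eqn{\tau} of the Gaussian tail
#'   (log10 units); default 0.05, well below typical viable-count noise so
#'   the tail acts as a soft barrier.
#' @return Log-likelihood contribution(s), same length as `predicted`.
#' @export
loglik_censored_point <- function(predicted, threshold, tail_sd = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(tail_sd) || length(tail_sd) != 1L || tail_sd <= 0) {
    stop("`tail_sd` must be a single positive number.", call. = FALSE)
  }
  excess <- pmax(0, predicted - threshold)
  -log(threshold) - excess^2 / (2 * tail_sd^2)
}

#' Log-likelihood of a full growth curve
#'
#' Sums the Gaussian log-likelihood over uncensored points and the
#' below-detection contribution over censored points.
#'
#' @inheritParams loglik_gaussian
#' @param tail_sd Gaussian-tail standard deviation for censored points, see
#'   [loglik_censored_point()].
#' @return Log-likelihood (a single number).
#' @export
loglik_curve <- function(curve, params, sigma, tail_sd = 0.05) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  p <- convert_scale(params, to = "log10")
  pred <- growth_predict(curve$time, p)
  cens <- curve$censored
  ll <- 0
  if (any(!cens)) ll <- ll + .ll_gauss(curve$logc[!cens], pred[!cens], sigma)
  if (any(cens)) {
    thr <- detection_threshold(curve)
    ll <- ll + sum(loglik_censored_point(pred[cens], thr, tail_sd))
  }
  ll
}

#' Joint log-likelihood of two growth curves
#'
#' The two curves are independent given their parameters, so the joint
#' log-likelihood is the sum of the individual curve log-likelihoods; a
#' single noise level is shared between the curves.
#'
#' @param curve_a,curve_b [growth_curve()] objects.
#' @param params_a,params_b [growth_params()] for each curve.
#' @inheritParams loglik_curve
#' @return Log-likelihood (a single number), symmetric under swapping the
#'   (curve, params) pairs.
#' @export
loglik_joint <- function(curve_a, curve_b, params_a, params_b, sigma,
                         tail_sd = 0.05) {
  loglik_curve(curve_a, params_a, sigma, tail_sd) +
    loglik_curve(curve_b, params_b, sigma, tail_sd)
}

# Compiled single-curve log-likelihood for sampler hot loops.
# Returns function(theta4, sigma) with theta4 = (y0, mu_max, h0, ymax) on
# the log10 scale; all curve constants are captured once.
.compile_curve_loglik <- function(curve, tail_sd = 0.05) {
  time <- curve$time
  d <- curve$logc
  cens <- curve$censored
  any_cens <- any(cens)
  thr <- detection_threshold(curve)
  d_unc <- d[!cens]
  t_all <- time
  idx_unc <- which(!cens)
  idx_cen <- which(cens)
  n_unc <- length(d_unc)
  half_log2pi <- 0.5 * log(2 * pi)
  function(theta4, sigma) {
    pred <- .predict_log10(t_all, theta4)
    ll <- -n_unc * (log(sigma) + half_log2pi) -
      sum((d_unc - pred[idx_unc])^2) / (2 * sigma^2)
    if (any_cens) {
      excess <- pmax(0, pred[idx_cen] - thr)
      ll <- ll - length(idx_cen) * log(thr) -
        sum(excess^2) / (2 * tail_sd^2)
    }
    ll
  }
}
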