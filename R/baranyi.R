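#' @keywords internal
LN10 <- log(10)

#' Baranyi-Roberts adjustment function
#'
#' Evaluates the adjustment function \eqn{A(t)} of the Baranyi-Roberts growth
#' model,
#' \deqn{A(t) = t - h_0/\mu_{max} +
#'   \ln(1 - e^{-\mu_{max} t} + e^{-(\mu_{max} t - h_0)}) / \mu_{max},}
#' which interpolates between \eqn{A(t) \approx 0} during the lag phase and
#' the asymptote \eqn{A(t) \to t - \lambda} (with lag time
#' \eqn{\lambda = h_0/\mu_{max}}) once growth is underway. The interior
#' logarithm is computed with a log-sum-exp rearrangement so the function
#' stays finite for \eqn{\mu_{max} t} well beyond 700.
#'
#' @param t Vector of times (hours), non-negative.
#' @param mu_max Maximum specific growth rate (per hour), positive. Must be
#'   on the same logarithm scale as the concentrations it will be used with.
#' @param h0 Dimensionless lag parameter, \eqn{h_0 = \lambda \mu_{max}},
#'   non-negative.
#' @return Numeric vector, \eqn{A(t)}, same length as `t`.
#' @examples
#' baranyi_adjustment(0, mu_max = 0.5, h0 = 1)   # exactly 0
#' baranyi_adjustment(7, mu_max = 0.3, h0 = 0)   # exactly 7 (no lag)
#' @export
baranyi_adjustment <- function(t, mu_max, h0) {
  if (!is.numeric(mu_max) || length(mu_max) != 1L || !is.finite(mu_max) ||
      mu_max <= 0) {
    stop("`mu_max` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(h0) || length(h0) != 1L || !is.finite(h0) || h0 < 0) {
    stop("`h0` must be a single non-negative number.", call. = FALSE)
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative and finite.", call. = FALSE)
  }
  a <- mu_max * t
  # ln(1 - e^{-a} + e^{h0 - a}) = m + ln(e^{-m} - e^{-a-m} + e^{h0-a-m}),
  # m = max(0, h0 - a); every exponent is <= 0 so nothing overflows. The
  # grouping cancels the identical e^{-m} terms exactly at t = 0, making
  # A(0) = 0 to the last bit.
  m <- pmax(0, h0 - a)
  w <- m + log((exp(-m) - exp(-a - m)) + exp(h0 - a - m))
  t - h0 / mu_max + w / mu_max
}

# Core Baranyi-Roberts prediction on the natural-log scale; `ymax = Inf`
# gives the no-stationary-phase variant. No argument validation: this is
# the sampler hot path (public wrappers validate).
.baranyi_ln <- function(t, y0, mu_max, h0, ymax) {
  a <- mu_max * t
  if (h0 == 0) {
    b <- a
  } else {
    # b = mu*A(t) = a - h0 + ln(1 - e^{-a} + e^{h0 - a}), log-sum-exp form;
    # term grouping keeps the cancellations exact at t = 0
    m <- h0 - a
    m <- m * (m > 0)
    b <- a - h0 + m + log((exp(-m) - exp(-a - m)) + exp(h0 - a - m))
  }
  if (is.infinite(ymax)) {
    return(y0 + b)
  }
  delta <- ymax - y0
  # ln(1 + e^{b - delta} - e^{-delta}), stable for large b; grouping makes
  # the e^{-delta} terms cancel exactly at b = 0 so y(0) = y0 to the bit
  m2 <- b - delta
  m2 <- m2 * (m2 > 0)
  s <- m2 + log(exp(-m2) + (exp(b - delta - m2) - exp(-delta - m2)))
  y0 + b - s
}

#' Construct a Baranyi-Roberts parameter set
#'
#' Bundles the four parameters of the Baranyi-Roberts growth model. The
#' `scale` records whether concentrations (and hence `y0`, `ymax` and
#' `mu_max`) are expressed in natural-log or log10 units; `h0` is
#' dimensionless and identical on both scales, so the lag time is always
#' \eqn{\lambda = h_0 / \mu_{max}^{(\ln)}}.
#'
#' @param y0 Log cell concentration at time zero.
#' @param mu_max Maximum specific growth rate (per hour), positive.
#' @param h0 Dimensionless lag parameter (`lag time * mu_max` on the
#'   natural-log scale), non-negative. Use 0 for the no-lag variant.
#' @param ymax Log maximum cell concentration; must exceed `y0`. Use `Inf`
#'   for the no-stationary-phase variant.
#' @param scale `"log10"` (default, the usual reporting scale for viable
#'   counts) or `"ln"`.
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(y0 = 3, mu_max = 0.11, h0 = 1, ymax = 9)
#' @export
growth_params <- function(y0, mu_max, h0, ymax, scale = c("log10", "ln")) {
  scale <- match.arg(scale)
  for (nm in c("y0", "mu_max", "h0", "ymax")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("`%s` must be a single number.", nm), call. = FALSE)
    }
  }
  if (mu_max <= 0) stop("`mu_max` must be positive.", call. = FALSE)
  if (h0 < 0) stop("`h0` must be non-negative.", call. = FALSE)
  if (ymax <= y0) stop("`ymax` must exceed `y0`.", call. = FALSE)
  structure(
    list(y0 = y0, mu_max = mu_max, h0 = h0, ymax = ymax, scale = scale),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "Baranyi-Roberts parameters (%s scale):\n  y0 = %g, mu_max = %g /h, h0 = %g, ymax = %g\n  lag time = %g h\n",
    x$scale, x$y0, x$mu_max, x$h0, x$ymax, lag_time(x)
  ))
  invisible(x)
}

#' Lag time implied by a parameter set
#'
#' The lag time in hours, \eqn{\lambda = h_0 / \mu_{max}} with
#' \eqn{\mu_{max}} on the natural-log scale (so for log10-scale parameters
#' \eqn{\lambda = h_0 / (\mu_{max} \ln 10)}).
#'
#' @param params A [growth_params()] object.
#' @return Lag time in hours.
#' @export
lag_time <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  mu_ln <- if (params$scale == "ln") params$mu_max else params$mu_max * LN10
  params$h0 / mu_ln
}

#' Predict log cell concentration under the Baranyi-Roberts model
#'
#' Evaluates
#' \deqn{y(t) = y_0 + \mu_{max} A(t) -
#'   \ln(1 + (e^{\mu_{max} A(t)} - 1)/e^{y_{max} - y_0})}
#' on the natural-log scale, converting the result back to the scale the
#' parameters were supplied on. The saturation logarithm is rearranged in
#' log-sum-exp form so predictions stay finite far into stationary phase.
#'
#' @param t Vector of times (hours), non-negative.
#' @param params A [growth_params()] object.
#' @return Predicted log concentrations on `params$scale`, one per time.
#' @examples
#' p <- growth_params(y0 = 3, mu_max = 0.11, h0 = 1, ymax = 9)
#' growth_predict(c(0, 10, 100), p)
#' @export
growth_predict <- function(t, params) {
  stopifnot(inherits(params, "growth_params"))
  p <- convert_scale(params, to = "ln")
  y_ln <- .baranyi_ln(t, p$y0, p$mu_max, p$h0, p$ymax)
  if (params$scale == "log10") y_ln / LN10 else y_ln
}

#' Convert values or parameter sets between log scales
#'
#' Concentrations, `y0`, `ymax` and `mu_max` are multiplied by
#' \eqn{\ln 10} when going from log10 to natural log (divided in the other
#' direction); `h0`, being dimensionless, is left unchanged. Round trips are
#' exact to machine precision.
#'
#' @param x A numeric vector of log concentrations, or a [growth_params()]
#'   object (whose own `scale` field is used as the source scale).
#' @param from,to Source and target scales, `"ln"` or `"log10"`. For
#'   `growth_params` input only `to` is consulted.
#' @return Converted object of the same type.
#' @examples
#' convert_scale(log(1000), from = "ln", to = "log10")  # 3
#' @export
convert_scale <- function(x, from = c("log10", "ln"), to = c("ln", "log10")) {
  UseMethod("convert_scale")
}

#' @export
convert_scale.numeric <- function(x, from = c("log10", "ln"),
                                  to = c("ln", "log10")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "log10") x * LN10 else x / LN10
}

#' @export
convert_scale.growth_params <- function(x, from = NULL,
                                        to = c("ln", "log10")) {
  to <- match.arg(to)
  if (x$scale == to) return(x)
  f <- if (to == "ln") LN10 else 1 / LN10
  structure(
    list(y0 = x$y0 * f, mu_max = x$mu_max * f, h0 = x$h0,
         ymax = x$ymax * f, scale = to),
    class = "growth_params"
  )
}

# Fast path used by likelihood code: parameters as an unnamed numeric
# vector (y0, mu_max, h0, ymax) on the log10 scale -> predicted log10
# values. Avoids S3 dispatch inside sampler loops.
.predict_log10 <- function(t, theta) {
  .baranyi_ln(t, theta[1L] * LN10, theta[2L] * LN10, theta[3L],
              theta[4L] * LN10) / LN10
}

#' Free parameters of the growth-model variants
#'
#' The full Baranyi-Roberts model has four parameters; restricted variants
#' drop the lag phase (`h0 = 0`), the stationary phase (`ymax = Inf`), or
#' both (pure exponential growth on the log scale).
#'
#' @param model One of `"baranyi"`, `"no_lag"`, `"no_stationary"`,
#'   `"exponential"`.
#' @return Character vector of free parameter names.
#' @export
model_free_params <- function(model = c("baranyi", "no_lag",
                                        "no_stationary", "exponential")) {
  model <- match.arg(model)
  switch(model,
    baranyi       = c("y0", "mu_max", "h0", "ymax"),
    no_lag        = c("y0", "mu_max", "ymax"),
    no_stationary = c("y0", "mu_max", "h0"),
    exponential   = c("y0", "mu_max")
  )
}
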