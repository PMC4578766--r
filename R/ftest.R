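#' Least-squares growth-model fits for a pair of curves
#'
#' Minimizes the summed squared residuals on the log10 scale with the full
#' four-parameter model. In the `separated` tying the two curves are fitted
#' independently (8 parameters); in the `unified` tying each curve keeps
#' its own `y0`, `h0` and `ymax` but a single growth rate is shared
#' (7 parameters). Optimization is multistart box-constrained local search
#' (`nlminb`): one heuristic start built from the data plus random starts
#' within the data-scaled default bounds, keeping the best.
#'
#' @param curve_a A [growth_curve()].
#' @param curve_b Optional second [growth_curve()]; omit for a single-curve
#'   fit (then `tying` is ignored).
#' @param tying `"separated"` or `"unified"`.
#' @param n_starts Number of optimization starts (default 10).
#' @param seed Optional seed for the random starts.
#' @return A list with `tying`, `par` (named vector, or list `a`/`b` for
#'   separated fits), `fitted` (list of fitted-value vectors), `ssr`
#'   (total summed squared residuals) and `convergence` (0 = at least one
#'   start converged).
#' @export
fit_growth_lsq <- function(curve_a, curve_b = NULL,
                           tying = c("separated", "unified"),
                           n_starts = 10, seed = NULL) {
  stopifnot(inherits(curve_a, "growth_curve"))
  tying <- match.arg(tying)
  if (!is.null(seed)) withr::local_seed(seed)

  if (is.null(curve_b)) {
    fit <- .lsq_one(curve_a, n_starts)
    return(list(tying = "single", par = fit$par,
                fitted = list(a = fit$fitted), ssr = fit$ssr,
                convergence = fit$convergence))
  }
  stopifnot(inherits(curve_b, "growth_curve"))

  if (tying == "separated") {
    fa <- .lsq_one(curve_a, n_starts)
    fb <- .lsq_one(curve_b, n_starts)
    list(tying = "separated",
         par = list(a = fa$par, b = fb$par),
         fitted = list(a = fa$fitted, b = fb$fitted),
         ssr = fa$ssr + fb$ssr,
         convergence = max(fa$convergence, fb$convergence))
  } else {
    .lsq_unified(curve_a, curve_b, n_starts)
  }
}

# The F statistic from observed values and the two models' fitted values:
# numerator sum (y_u - y_s)^2, denominator sum (d - y_s)^2 / (N1 + N2 - 1),
# referred to F(1, N - 7). The conventional variant is the textbook
# extra-sum-of-squares ratio on F(1, N - 8).
.f_statistic <- function(d, y_s, y_u, conventional = FALSE,
                         ssr_s = sum((d - y_s)^2),
                         ssr_u = sum((d - y_u)^2)) {
  n <- length(d)
  if (conventional) {
    list(num = max(ssr_u - ssr_s, 0), den = ssr_s / (n - 8L),
         df1 = 1L, df2 = n - 8L)
  } else {
    list(num = sum((y_u - y_s)^2), den = sum((d - y_s)^2) / (n - 1L),
         df1 = 1L, df2 = n - 7L)
  }
}

# Box bounds for least-squares fitting, from the data-scaled prior rules.
.lsq_bounds <- function(curve) {
  dp <- default_priors(curve, sigma = "fixed")
  list(lower = vapply(dp, `[[`, numeric(1), "lower"),
       upper = vapply(dp, `[[`, numeric(1), "upper"))
}

.lsq_heuristic_start <- function(curve, bounds) {
  slopes <- diff(curve$logc) / diff(curve$time)
  mu0 <- max(c(slopes, 0.01))
  start <- c(y0 = min(curve$logc), mu_max = mu0, h0 = 1,
             ymax = max(curve$logc) + 0.1)
  pmin(pmax(start, bounds$lower + 1e-9), bounds$upper - 1e-9)
}

.lsq_one <- function(curve, n_starts) {
  b <- .lsq_bounds(curve)
  time <- curve$time
  d <- curve$logc
  obj <- function(th) {
    if (th[4L] <= th[1L]) return(1e10)
    sum((d - .predict_log10(time, th))^2)
  }
  starts <- list(.lsq_heuristic_start(curve, b))
  for (i in seq_len(max(n_starts - 1L, 0L))) {
    starts[[i + 1L]] <- b$lower + stats::runif(4L) * (b$upper - b$lower)
  }
  best <- NULL
  conv <- 1L
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, obj, lower = b$lower, upper = b$upper),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0L) conv <- 0L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    stop("Least-squares fit failed from every start.", call. = FALSE)
  }
  par <- stats::setNames(best$par, c("y0", "mu_max", "h0", "ymax"))
  list(par = par, fitted = .predict_log10(time, best$par),
       ssr = best$objective, convergence = conv)
}

.lsq_unified <- function(curve_a, curve_b, n_starts) {
  ba <- .lsq_bounds(curve_a)
  bb <- .lsq_bounds(curve_b)
  # theta = (y0_a, h0_a, ymax_a, y0_b, h0_b, ymax_b, mu_max)
  lower <- c(ba$lower[c("y0", "h0", "ymax")], bb$lower[c("y0", "h0", "ymax")],
             min(ba$lower["mu_max"], bb$lower["mu_max"]))
  upper <- c(ba$upper[c("y0", "h0", "ymax")], bb$upper[c("y0", "h0", "ymax")],
             max(ba$upper["mu_max"], bb$upper["mu_max"]))
  ta <- curve_a$time
  tb <- curve_b$time
  da <- curve_a$logc
  db <- curve_b$logc
  obj <- function(th) {
    if (th[3L] <= th[1L] || th[6L] <= th[4L]) return(1e10)
    sum((da - .predict_log10(ta, c(th[1L], th[7L], th[2L], th[3L])))^2) +
      sum((db - .predict_log10(tb, c(th[4L], th[7L], th[5L], th[6L])))^2)
  }
  sa <- .lsq_heuristic_start(curve_a, ba)
  sb <- .lsq_heuristic_start(curve_b, bb)
  starts <- list(c(sa[c("y0", "h0", "ymax")], sb[c("y0", "h0", "ymax")],
                   mean(c(sa["mu_max"], sb["mu_max"]))))
  for (i in seq_len(max(n_starts - 1L, 0L))) {
    starts[[i + 1L]] <- lower + stats::runif(7L) * (upper - lower)
  }
  best <- NULL
  conv <- 1L
  for (s in starts) {
    fit <- tryCatch(stats::nlminb(s, obj, lower = lower, upper = upper),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) conv <- 0L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    stop("Least-squares fit failed from every start.", call. = FALSE)
  }
  th <- best$par
  par <- stats::setNames(th, c("y0_a", "h0_a", "ymax_a",
                               "y0_b", "h0_b", "ymax_b", "mu_max"))
  list(tying = "unified", par = par,
       fitted = list(
         a = .predict_log10(ta, c(th[1L], th[7L], th[2L], th[3L])),
         b = .predict_log10(tb, c(th[4L], th[7L], th[5L], th[6L]))
       ),
       ssr = best$objective, convergence = conv)
}

#' F-test for a shared growth rate between two curves
#'
#' The frequentist baseline: both curves are fitted by least squares under
#' the separated (8-parameter) and unified (7-parameter, shared rate)
#' models and the statistic
#' \deqn{F = \frac{\sum_i (y_i^u - y_i^s)^2}
#'   {\sum_i (d_i - y_i^s)^2 / (N_1 + N_2 - 1)}}
#' is referred to the F distribution with `df1 = 1` (the parameter-count
#' difference) and `df2 = N1 + N2 - 7` (points minus unified parameters).
#' The null hypothesis (equal growth rates) is rejected when the upper-tail
#' probability falls below `threshold`. `conventional = TRUE` switches to
#' the textbook extra-sum-of-squares statistic
#' `((SSR_u - SSR_s)/1) / (SSR_s/(N-8))` with `df2 = N - 8`.
#'
#' @inheritParams fit_growth_lsq
#' @param threshold Rejection threshold for the p-value (default 0.05).
#' @param conventional Use the conventional extra-sum-of-squares form.
#' @return A `growth_f_test` object with `statistic`, `df1`, `df2`,
#'   `p_value`, `reject_null`, `degenerate` (perfect separated fit), and
#'   the two fits.
#' @export
growth_f_test <- function(curve_a, curve_b, n_starts = 10, seed = NULL,
                          threshold = 0.05, conventional = FALSE) {
  stopifnot(inherits(curve_a, "growth_curve"),
            inherits(curve_b, "growth_curve"))
  if (!is.null(seed)) withr::local_seed(seed)
  sep <- fit_growth_lsq(curve_a, curve_b, "separated", n_starts)
  uni <- fit_growth_lsq(curve_a, curve_b, "unified", n_starts)
  d <- c(curve_a$logc, curve_b$logc)
  y_s <- c(sep$fitted$a, sep$fitted$b)
  y_u <- c(uni$fitted$a, uni$fitted$b)
  fs <- .f_statistic(d, y_s, y_u, conventional = conventional,
                     ssr_s = sep$ssr, ssr_u = uni$ssr)
  df1 <- fs$df1
  df2 <- fs$df2
  num <- fs$num
  den <- fs$den
  degenerate <- FALSE
  if (den <= 0) {
    degenerate <- TRUE
    statistic <- Inf
    p_value <- 0
  } else {
    statistic <- num / den
    p_value <- stats::pf(statistic, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(statistic = statistic, df1 = df1, df2 = df2, p_value = p_value,
         reject_null = p_value < threshold, threshold = threshold,
         degenerate = degenerate, conventional = conventional,
         separated = sep, unified = uni),
    class = "growth_f_test"
  )
}

#' @export
print.growth_f_test <- function(x, ...) {
  cat(sprintf(
    "F-test for equal growth rates: F = %.4g on (%d, %d) df, p = %.4g\n%s\n",
    x$statistic, x$df1, x$df2, x$p_value,
    if (x$reject_null) {
      sprintf("Growth rates differ at the %.2g level.", x$threshold)
    } else {
      sprintf("No significant difference at the %.2g level.", x$threshold)
    }
  ))
  if (x$degenerate) cat("(degenerate: perfect separated fit)\n")
  invisible(x)
}

#' Tidy an F-test result
#'
#' @param x A `growth_f_test`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p.value`,
#'   `reject_null`, `degenerate`.
#' @method tidy growth_f_test
#' @export
tidy.growth_f_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value, reject_null = x$reject_null,
                 degenerate = x$degenerate)
}

#' @method glance growth_f_test
#' @export
glance.growth_f_test <- function(x, ...) tidy(x)
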