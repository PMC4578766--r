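#' Construct a growth curve
#'
#' A growth curve is a tibble with columns `time` (hours, strictly
#' increasing), `logc` (log10 cell concentration) and `censored` (logical;
#' `TRUE` marks an observation below the detection limit). Curves with any
#' censored point must carry a detection `threshold` (log10 scale); the
#' paper's viable-count thresholds of 0.7 and 1.3 are typical values.
#'
#' @param data A data frame with columns `time`, `logc` and optionally
#'   `censored` (logical or 0/1).
#' @param threshold Detection threshold on the log10 scale, required when
#'   any observation is censored.
#' @return A tibble of class `growth_curve` with a `threshold` attribute.
#' @examples
#' growth_curve(data.frame(time = c(0, 2, 4), logc = c(3.1, 3.2, 3.9)))
#' @export
growth_curve <- function(data, threshold = NULL) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame.", call. = FALSE)
  }
  if (!all(c("time", "logc") %in% names(data))) {
    stop("`data` needs columns `time` and `logc`.", call. = FALSE)
  }
  time <- as.numeric(data$time)
  logc <- as.numeric(data$logc)
  censored <- if ("censored" %in% names(data)) {
    as.logical(data$censored)
  } else {
    rep(FALSE, length(time))
  }
  if (length(time) < 2L) {
    stop("A growth curve needs at least 2 observations.", call. = FALSE)
  }
  if (anyNA(time) || anyNA(logc) || anyNA(censored)) {
    stop("`time`, `logc` and `censored` must not contain missing values.",
         call. = FALSE)
  }
  if (any(time < 0)) {
    stop("Times must be non-negative.", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("Times must be strictly increasing.", call. = FALSE)
  }
  if (any(censored)) {
    if (is.null(threshold)) {
      stop("Curves with censored observations need a detection `threshold`.",
           call. = FALSE)
    }
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
      stop("`threshold` must be a single positive number (log10 scale).",
           call. = FALSE)
    }
    if (any(logc[censored] > threshold)) {
      stop("Censored observations must not exceed the detection threshold.",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(time = time, logc = logc, censored = censored)
  class(out) <- c("growth_curve", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Detection threshold of a growth curve
#'
#' @param curve A [growth_curve()].
#' @return The log10 detection threshold, or `NULL` if none was set.
#' @export
detection_threshold <- function(curve) {
  attr(curve, "threshold", exact = TRUE)
}

#' Read a growth curve from a delimited text file
#'
#' The file format is comma-separated with a header line `time,logc` or
#' `time,logc,censored`; `censored` is 0/1 (default 0). Malformed rows are
#' reported with their line numbers rather than silently dropped.
#'
#' @param path Path to the file.
#' @param threshold Detection threshold (log10), required when any row is
#'   censored.
#' @return A [growth_curve()].
#' @export
read_growth_curve <- function(path, threshold = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("File not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop(sprintf("%s: need a header line and at least 2 data rows.", path),
         call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[1L], ",")[[1L]]))
  if (!identical(header, c("time", "logc")) &&
      !identical(header, c("time", "logc", "censored"))) {
    stop(sprintf(
      "%s: bad header %s; expected 'time,logc' or 'time,logc,censored'.",
      path, sQuote(lines[1L])
    ), call. = FALSE)
  }
  ncol <- length(header)
  rows <- strsplit(lines[-1L], ",")
  bad <- character()
  parsed <- matrix(NA_real_, nrow = length(rows), ncol = 3L)
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    lineno <- i + 1L
    if (length(f) != ncol) {
      bad <- c(bad, sprintf("line %d: expected %d fields, got %d",
                            lineno, ncol, length(f)))
      next
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      bad <- c(bad, sprintf("line %d: non-numeric field", lineno))
      next
    }
    if (ncol == 3L && !v[3L] %in% c(0, 1)) {
      bad <- c(bad, sprintf("line %d: censored flag must be 0 or 1", lineno))
      next
    }
    parsed[i, seq_len(ncol)] <- v
  }
  if (length(bad) > 0L) {
    stop(sprintf("%s: parse errors:\n  %s", path,
                 paste(bad, collapse = "\n  ")), call. = FALSE)
  }
  df <- data.frame(
    time = parsed[, 1L],
    logc = parsed[, 2L],
    censored = if (ncol == 3L) parsed[, 3L] == 1 else FALSE
  )
  growth_curve(df, threshold = threshold)
}

#' Write a growth curve to a delimited text file
#'
#' Inverse of [read_growth_curve()]; the `censored` column is written only
#' when some observation is censored.
#'
#' @param curve A [growth_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_curve <- function(curve, path) {
  stopifnot(inherits(curve, "growth_curve"))
  if (any(curve$censored)) {
    lines <- c("time,logc,censored",
               sprintf("%.15g,%.15g,%d", curve$time, curve$logc,
                       as.integer(curve$censored)))
  } else {
    lines <- c("time,logc", sprintf("%.15g,%.15g", curve$time, curve$logc))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Time for a curve to complete a fraction of its total rise
#'
#' Solves \eqn{y(t) = y_0 + f (y_{max} - y_0)} numerically; used to choose
#' a sensible simulation horizon.
#'
#' @param params A [growth_params()] with finite `ymax`.
#' @param fraction Fraction of the rise, in (0, 1).
#' @return Time in hours.
#' @export
time_to_fraction <- function(params, fraction = 0.95) {
  stopifnot(inherits(params, "growth_params"),
            fraction > 0, fraction < 1, is.finite(params$ymax))
  target <- params$y0 + fraction * (params$ymax - params$y0)
  f <- function(t) growth_predict(t, params) - target
  upper <- 1
  while (f(upper) < 0 && upper < 1e8) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

#' Simulate a Baranyi-Roberts growth curve
#'
#' Observations are placed on an evenly spaced time grid over
#' `[0, t_max]`; i.i.d. Gaussian noise with standard deviation `sigma` is
#' added on the log10 scale (the error model appropriate for viable-count
#' data, whose concentration errors are log-normal). When a detection
#' `threshold` is given, noisy values falling below it are flagged as
#' censored.
#'
#' @param params A [growth_params()] on the log10 scale. Default: a
#'   viable-count-like curve rising from 3 to 9 log10 cfu at rate
#'   0.11 log10/h with `h0 = 1`.
#' @param n_points Number of observations (default 32).
#' @param t_max Time horizon in hours; default runs to 95 % of the rise.
#' @param sigma Noise standard deviation, log10 units (default 0.1).
#' @param threshold Optional detection threshold (log10).
#' @param seed Optional integer seed; the simulation is reproducible given
#'   the seed and leaves the global RNG state untouched.
#' @return A [growth_curve()].
#' @examples
#' simulate_growth_curve(seed = 1)
#' @export
simulate_growth_curve <- function(params = growth_params(3, 0.11, 1, 9),
                                  n_points = 32, t_max = NULL, sigma = 0.1,
                                  threshold = NULL, seed = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (params$scale != "log10") params <- convert_scale(params, to = "log10")
  if (!is.numeric(n_points) || n_points < 2L) {
    stop("`n_points` must be at least 2.", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number.", call. = FALSE)
  }
  if (is.null(t_max)) t_max <- time_to_fraction(params, 0.95)
  if (t_max <= 0) stop("`t_max` must be positive.", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  times <- seq(0, t_max, length.out = n_points)
  mu <- growth_predict(times, params)
  logc <- mu + stats::rnorm(n_points, 0, sigma)
  censored <- if (!is.null(threshold)) logc < threshold else rep(FALSE, n_points)
  logc[censored] <- pmin(logc[censored], threshold)
  growth_curve(
    data.frame(time = times, logc = logc, censored = censored),
    threshold = threshold
  )
}
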