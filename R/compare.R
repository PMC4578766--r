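#' Jeffreys' scale for Bayes factors
#'
#' Maps `2 ln B` onto Jeffreys' qualitative bands of evidence against the
#' competing hypothesis: `[0, 2)` "hardly worth mentioning", `[2, 6)` "has
#' some substance", `[6, 10)` "strong", `>= 10` "very strong". A negative
#' value is evidence in the other direction; it is categorised by its
#' magnitude and flagged as reversed.
#'
#' @param two_ln_b Numeric vector of `2 ln B` values (finite).
#' @return Character vector of category labels.
#' @examples
#' jeffreys_category(c(1, 7, 12))
#' @export
jeffreys_category <- function(two_ln_b) {
  if (any(is.nan(two_ln_b)) || any(is.na(two_ln_b))) {
    stop("`two_ln_b` must not contain NaN/NA.", call. = FALSE)
  }
  band <- function(x) {
    if (x < 2) "hardly worth mentioning"
    else if (x < 6) "has some substance"
    else if (x < 10) "strong"
    else "very strong"
  }
  vapply(two_ln_b, function(x) {
    lab <- band(abs(x))
    if (x < 0) paste0(lab, " (reversed)") else lab
  }, character(1))
}

# Union of two uniform entries' bounds.
.union_uniform <- function(a, b) prior_uniform(min(a$lower, b$lower),
                                               max(a$upper, b$upper))

.truncate_entry <- function(entry, lower, upper) {
  if (is.null(entry)) return(NULL)
  if (entry$dist %in% c("gaussian", "cauchy")) {
    entry$lower <- max(entry$lower, lower)
    entry$upper <- min(entry$upper, upper)
  }
  entry
}

# Normalize the mu_prior argument into list(a =, b =, shared =).
.mu_priors <- function(mu_prior) {
  if (is.null(mu_prior)) return(list(a = NULL, b = NULL, shared = NULL))
  if (inherits(mu_prior, "prior_entry")) {
    return(list(a = mu_prior, b = mu_prior, shared = mu_prior))
  }
  stopifnot(is.list(mu_prior),
            all(names(mu_prior) %in% c("a", "b", "shared")))
  list(a = mu_prior$a, b = mu_prior$b, shared = mu_prior$shared)
}

.derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + i * 1000003) %% 2147483563) + 1L
}

#' Compare two growth curves by Bayes factors
#'
#' Scores up to three hypotheses for a pair of curves by their model
#' evidence: H1, the curves are replicates (one shared parameter set); H2,
#' the curves share the growth rate but differ in all other parameters;
#' H3, the curves share no parameters. Each hypothesis is scored by one
#' nested-sampling run on the joint likelihood (a single noise level is
#' shared across the two curves within a hypothesis), and pairwise Bayes
#' factors \eqn{\ln B_{ij} = \ln Z_i - \ln Z_j} are interpreted on
#' Jeffreys' scale. The growth rates are declared different when there is
#' substantial evidence for H3 over H2, i.e. `2 ln B32 >= 2`.
#'
#' @param curve_a,curve_b [growth_curve()] objects.
#' @param hypotheses Subset of `c("H1", "H2", "H3")` to score.
#' @param mu_prior Optional informative prior for the growth rate: a single
#'   `prior_entry` applied everywhere, or a list with elements `a`, `b`
#'   (per-curve rates under H3) and `shared` (the common rate under
#'   H1/H2). Unbounded informative entries are truncated to the union of
#'   the two curves' data-scaled bounds.
#' @param noise `"inferred"` (default) or `"fixed"`.
#' @param sigma Noise sd (log10) when `noise = "fixed"`.
#' @param tail_sd Gaussian-tail sd for censored points.
#' @param config An [ns_config()]; per-hypothesis seeds are derived from
#'   `config$seed` so a seeded comparison is reproducible.
#' @return A `growth_comparison` object: `evidence` (tibble, one row per
#'   hypothesis), `two_ln_b` (matrix of `2 ln B_ij`), `categories`
#'   (Jeffreys labels for the matrix), `verdict` (`"different"`/`"same"`
#'   when H2 and H3 were scored), and the per-hypothesis `fits`
#'   (`ns_result` objects).
#' @export
compare_growth_rates <- function(curve_a, curve_b,
                                 hypotheses = c("H1", "H2", "H3"),
                                 mu_prior = NULL,
                                 noise = c("inferred", "fixed"),
                                 sigma = NULL, tail_sd = 0.05,
                                 config = ns_config()) {
  stopifnot(inherits(curve_a, "growth_curve"),
            inherits(curve_b, "growth_curve"))
  noise <- match.arg(noise)
  hypotheses <- match.arg(hypotheses, several.ok = TRUE)
  if (noise == "fixed" &&
      (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)) {
    stop("`noise = \"fixed\"` requires a positive `sigma`.", call. = FALSE)
  }
  dp_a <- default_priors(curve_a)
  dp_b <- default_priors(curve_b)
  mu_union <- .union_uniform(dp_a$mu_max, dp_b$mu_max)
  mp <- .mu_priors(mu_prior)
  mp$a <- .truncate_entry(mp$a, dp_a$mu_max$lower, dp_a$mu_max$upper) %||%
    dp_a$mu_max
  mp$b <- .truncate_entry(mp$b, dp_b$mu_max$lower, dp_b$mu_max$upper) %||%
    dp_b$mu_max
  mp$shared <- .truncate_entry(mp$shared, mu_union$lower, mu_union$upper) %||%
    mu_union
  sigma_entry <- prior_jeffreys(
    min(dp_a$sigma$lower, dp_b$sigma$lower),
    max(dp_a$sigma$upper, dp_b$sigma$upper)
  )

  ll_a <- .compile_curve_loglik(curve_a, tail_sd)
  ll_b <- .compile_curve_loglik(curve_b, tail_sd)
  infer <- noise == "inferred"
  sigma_fixed <- sigma

  builders <- list(
    H1 = function() {
      entries <- list(
        y0 = .union_uniform(dp_a$y0, dp_b$y0),
        mu_max = mp$shared,
        h0 = .union_uniform(dp_a$h0, dp_b$h0),
        ymax = .union_uniform(dp_a$ymax, dp_b$ymax)
      )
      if (infer) entries$sigma <- sigma_entry
      spec <- do.call(prior_spec, entries)
      loglik <- function(th) {
        if (th[4L] <= th[1L]) return(-Inf)
        s <- if (infer) th[5L] else sigma_fixed
        th4 <- th[1:4]
        ll_a(th4, s) + ll_b(th4, s)
      }
      list(spec = spec, loglik = loglik)
    },
    H2 = function() {
      entries <- list(
        y0_a = dp_a$y0, h0_a = dp_a$h0, ymax_a = dp_a$ymax,
        y0_b = dp_b$y0, h0_b = dp_b$h0, ymax_b = dp_b$ymax,
        mu_max = mp$shared
      )
      if (infer) entries$sigma <- sigma_entry
      spec <- do.call(prior_spec, entries)
      loglik <- function(th) {
        if (th[3L] <= th[1L] || th[6L] <= th[4L]) return(-Inf)
        s <- if (infer) th[8L] else sigma_fixed
        ll_a(c(th[1L], th[7L], th[2L], th[3L]), s) +
          ll_b(c(th[4L], th[7L], th[5L], th[6L]), s)
      }
      list(spec = spec, loglik = loglik)
    },
    H3 = function() {
      entries <- list(
        y0_a = dp_a$y0, mu_max_a = mp$a, h0_a = dp_a$h0, ymax_a = dp_a$ymax,
        y0_b = dp_b$y0, mu_max_b = mp$b, h0_b = dp_b$h0, ymax_b = dp_b$ymax
      )
      if (infer) entries$sigma <- sigma_entry
      spec <- do.call(prior_spec, entries)
      loglik <- function(th) {
        if (th[4L] <= th[1L] || th[8L] <= th[5L]) return(-Inf)
        s <- if (infer) th[9L] else sigma_fixed
        ll_a(th[1:4], s) + ll_b(th[5:8], s)
      }
      list(spec = spec, loglik = loglik)
    }
  )

  fits <- list()
  for (h in hypotheses) {
    built <- builders[[h]]()
    cfg <- config
    cfg$seed <- .derive_seed(config$seed, match(h, c("H1", "H2", "H3")))
    fits[[h]] <- nested_sample(built$loglik, built$spec, cfg)
  }

  evidence <- purrr::map_dfr(hypotheses, function(h) {
    f <- fits[[h]]
    tibble::tibble(
      hypothesis = h,
      log_evidence = f$log_evidence,
      log_evidence_sd = f$log_evidence_sd,
      information = f$information,
      n_iterations = f$n_iterations,
      converged = f$converged
    )
  })

  lnz <- stats::setNames(evidence$log_evidence, evidence$hypothesis)
  two_ln_b <- outer(lnz, lnz, function(a, b) 2 * (a - b))
  categories <- matrix(jeffreys_category(as.vector(two_ln_b)),
                       nrow = nrow(two_ln_b),
                       dimnames = dimnames(two_ln_b))
  verdict <- if (all(c("H2", "H3") %in% hypotheses)) {
    if (two_ln_b["H3", "H2"] >= 2) "different" else "same"
  } else {
    NA_character_
  }

  structure(
    list(evidence = evidence, two_ln_b = two_ln_b, categories = categories,
         verdict = verdict, fits = fits, mu_prior = mp, noise = noise,
         config = config),
    class = "growth_comparison"
  )
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat("Bayesian growth-rate comparison\n")
  print(as.data.frame(x$evidence), row.names = FALSE)
  cat("\n2 ln B (row vs column):\n")
  print(round(x$two_ln_b, 2))
  if (!is.na(x$verdict)) {
    cat(sprintf(
      "\nVerdict: growth rates judged %s (2 ln B32 = %.2f, %s)\n",
      x$verdict, x$two_ln_b["H3", "H2"],
      jeffreys_category(x$two_ln_b["H3", "H2"])
    ))
  }
  invisible(x)
}

#' Tidy a growth-rate comparison
#'
#' @param x A `growth_comparison`.
#' @param ... Unused.
#' @return The per-hypothesis evidence tibble.
#' @method tidy growth_comparison
#' @export
tidy.growth_comparison <- function(x, ...) x$evidence

#' Glance at a growth-rate comparison
#'
#' @param x A `growth_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with per-hypothesis evidences, `two_ln_b32`
#'   and the verdict.
#' @method glance growth_comparison
#' @export
glance.growth_comparison <- function(x, ...) {
  lnz <- stats::setNames(x$evidence$log_evidence, x$evidence$hypothesis)
  tibble::tibble(
    log_z_h1 = unname(lnz["H1"]) %||% NA_real_,
    log_z_h2 = unname(lnz["H2"]) %||% NA_real_,
    log_z_h3 = unname(lnz["H3"]) %||% NA_real_,
    two_ln_b32 = if (all(c("H2", "H3") %in% names(lnz)))
      2 * (lnz[["H3"]] - lnz[["H2"]]) else NA_real_,
    verdict = x$verdict
  )
}
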