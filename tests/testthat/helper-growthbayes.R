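# Shared fixtures and small utilities for the test suite.

base_params <- function(mu = 0.11) growth_params(3, mu, 1, 9)

base_t_max <- function() time_to_fraction(base_params(), 0.95)

# Quick sampler settings for unit tests (acceptance tests choose their own).
quick_config <- function(seed, n_live = 50) {
  ns_config(n_live = n_live, seed = seed)
}

# A tiny hand-made ns_result for testing the summary operations without
# running the sampler.
fake_ns_result <- function(values, weights) {
  weights <- weights / sum(weights)
  structure(
    list(
      log_evidence = 0, log_evidence_sd = 0, information = 0,
      samples = tibble::tibble(p = values, log_lik = 0,
                               log_width = log(weights), weight = weights),
      n_iterations = length(values), n_live = 2, converged = TRUE,
      parameters = "p"
    ),
    class = "ns_result"
  )
}

random_valid_params <- function() {
  y0 <- stats::runif(1, -2, 6)
  growth_params(
    y0 = y0,
    mu_max = stats::runif(1, 0.01, 2),
    h0 = stats::runif(1, 0, 5),
    ymax = y0 + stats::runif(1, 0.5, 10)
  )
}
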