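#' Read a cluster file of previously analysed growth rates
#'
#' Comma-separated rows `mean,variance` (with that header), one per
#' previously analysed curve; the values are the posterior mean and
#' variance of `mu_max` on the log10 scale, ready for [cluster_prior()].
#'
#' @param path Path to the file.
#' @return A tibble with columns `mean` and `variance`.
#' @export
read_cluster_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("File not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, strip.white = TRUE)
  if (!all(c("mean", "variance") %in% names(df))) {
    stop(sprintf("%s: expected header 'mean,variance'.", path), call. = FALSE)
  }
  if (nrow(df) < 1L || anyNA(df$mean) || anyNA(df$variance) ||
      any(df$variance < 0)) {
    stop(sprintf("%s: need >= 1 row of finite mean and non-negative variance.",
                 path), call. = FALSE)
  }
  tibble::as_tibble(df[c("mean", "variance")])
}

# Serializable form of a prior entry (exact numeric echo on round-trip).
.entry_to_list <- function(entry) {
  unclass(entry)
}

.entry_from_list <- function(x, name = "prior") {
  if (!is.list(x) || is.null(x$dist)) {
    stop(sprintf("Prior entry `%s` needs a `dist` field.", name),
         call. = FALSE)
  }
  switch(x$dist,
    uniform = prior_uniform(x$lower, x$upper),
    jeffreys = prior_jeffreys(x$lower, x$upper),
    gaussian = prior_gaussian(x$mean, x$sd, x$lower %||% -Inf,
                              x$upper %||% Inf),
    cauchy = prior_cauchy(x$location, x$scale, x$lower %||% -Inf,
                          x$upper %||% Inf),
    stop(sprintf("Unknown prior distribution `%s` in entry `%s`.",
                 x$dist, name), call. = FALSE)
  )
}

.run_config_defaults <- function() {
  list(
    model = "baranyi",
    noise = list(mode = "inferred", sigma = NULL),
    threshold = NULL,
    tail_sd = 0.05,
    priors = NULL,
    cluster_file = NULL,
    cluster_prior = "gaussian",
    sampler = list(n_live = 100, max_mcmc_steps = 20,
                   termination_tolerance = 1e-6, max_iterations = 1e5),
    seed = NULL
  )
}

#' Read a run configuration file
#'
#' YAML configuration for the command-line drivers. Recognised keys:
#' `model` (growth-model variant), `noise` (`mode`: inferred/fixed,
#' `sigma`), `threshold` (detection limit, log10), `tail_sd`, `priors`
#' (per-parameter entries, each with a `dist` field), `cluster_file`,
#' `cluster_prior` (gaussian/cauchy), `sampler` ([ns_config()] fields) and
#' `seed`. Unknown keys are rejected rather than ignored.
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .run_config_defaults()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop(sprintf("Config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("Unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (nm %in% c("noise", "sampler")) {
      sub <- user[[nm]]
      unknown <- setdiff(names(sub), names(cfg[[nm]]))
      if (length(unknown) > 0L) {
        stop(sprintf("Unknown `%s` config keys: %s", nm,
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      cfg[[nm]][names(sub)] <- sub
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!cfg$noise$mode %in% c("inferred", "fixed")) {
    stop("`noise.mode` must be 'inferred' or 'fixed'.", call. = FALSE)
  }
  if (!is.null(cfg$priors)) {
    cfg$priors <- purrr::imap(cfg$priors, .entry_from_list)
  }
  cfg
}

# ns_config from a run configuration, with optional seed override.
.config_sampler <- function(cfg, seed = NULL) {
  s <- cfg$sampler
  ns_config(n_live = s$n_live, max_mcmc_steps = s$max_mcmc_steps,
            termination_tolerance = s$termination_tolerance,
            max_iterations = s$max_iterations,
            seed = seed %||% cfg$seed)
}

# Effective-config echo for run manifests (JSON-ready list).
.config_manifest <- function(cfg, seed, extra = list()) {
  c(list(
    package_version = as.character(utils::packageVersion("growthbayes")),
    seed = seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = purrr::map(cfg, function(x) {
      if (is.list(x) && !is.null(x$dist)) .entry_to_list(x) else x
    })
  ), extra)
}
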