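#' Plot a growth curve
#'
#' Observations over time, with censored (below-detection) points drawn as
#' open triangles and the detection threshold as a dashed line.
#'
#' @param object A [growth_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_curve
#' @export
autoplot.growth_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$logc)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2),
                                guide = if (any(object$censored)) "legend"
                                        else "none") +
    ggplot2::labs(x = "time (h)", y = expression(log[10] ~ concentration),
                  shape = "censored") +
    ggplot2::theme_minimal()
  thr <- detection_threshold(object)
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot a Bayesian growth-curve fit
#'
#' Data overlaid with posterior trajectories (equally weighted draws
#' obtained by staircase resampling) and the posterior-mean curve.
#'
#' @param object A `growth_fit`.
#' @param draws Number of posterior trajectories to show (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, draws = 50, ...) {
  curve <- object$curve
  grid <- seq(min(curve$time), max(curve$time), length.out = 101)
  expand <- .theta_expander(names(object$spec), object$model)
  ss <- staircase_sample(object$ns, draws, seed = 1L)
  free <- intersect(names(object$spec), c("y0", "mu_max", "h0", "ymax"))
  traj <- purrr::map_dfr(seq_len(nrow(ss)), function(i) {
    th <- expand(unlist(ss[i, ]))
    tibble::tibble(draw = i, time = grid, logc = .predict_log10(grid, th))
  })
  ps <- posterior_summary(object$ns)
  mean_th <- expand(stats::setNames(ps$mean, ps$parameter)[names(object$spec)])
  mean_traj <- tibble::tibble(time = grid,
                              logc = .predict_log10(grid, mean_th))
  autoplot(curve) +
    ggplot2::geom_line(data = traj,
                       ggplot2::aes(group = .data$draw), alpha = 0.08,
                       colour = "steelblue") +
    ggplot2::geom_line(data = mean_traj, colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::labs(subtitle = sprintf("ln Z = %.2f +/- %.2f",
                                     object$ns$log_evidence,
                                     object$ns$log_evidence_sd))
}

#' Plot a growth-rate comparison
#'
#' Per-hypothesis log-evidence with its nested-sampling uncertainty.
#'
#' @param object A `growth_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_comparison
#' @export
autoplot.growth_comparison <- function(object, ...) {
  ev <- object$evidence
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$hypothesis,
                                   y = .data$log_evidence)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$log_evidence - .data$log_evidence_sd,
                   ymax = .data$log_evidence + .data$log_evidence_sd),
      width = 0.15
    ) +
    ggplot2::labs(x = NULL, y = "ln Z",
                  subtitle = if (!is.na(object$verdict)) {
                    sprintf("verdict: growth rates %s", object$verdict)
                  }) +
    ggplot2::theme_minimal()
}

#' Plot a detection-rate comparison table
#'
#' @param tbl Output of [detection_comparison()].
#' @return A ggplot object: percent correct vs noise level, one line per
#'   method.
#' @export
plot_detection_comparison <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$sigma,
                                    y = 100 * .data$prop_correct,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(sigma ~ "(log10 units)"),
                  y = "% correct", colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation sweep
#'
#' @param tbl Output of [perturbation_sweep()].
#' @return A ggplot object: mean ln B23 (same-rate over different-rate
#'   evidence) against the rate difference, with a +/- 1 sd ribbon and the
#'   substantial-evidence line at `2 ln B23 = -2`.
#' @export
plot_perturbation_sweep <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$delta_mu,
                                    y = .data$mean_ln_b23)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ln_b23 -
                                        .data$sd_ln_b23,
                                      ymax = .data$mean_ln_b23 +
                                        .data$sd_ln_b23),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = expression(Delta * mu[max]),
                  y = expression(ln ~ B[23])) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-ranking evidence sweep
#'
#' @param tbl Output of [cluster_ranking_sweep()].
#' @return A ggplot object: mean log-evidence against the target growth
#'   rate, one line per prior/cluster combination.
#' @export
plot_cluster_ranking <- function(tbl) {
  agg <- tbl |>
    dplyr::mutate(label = ifelse(is.na(.data$cluster), .data$prior,
                                 paste0(.data$prior, "-", .data$cluster))) |>
    dplyr::group_by(.data$target_mu, .data$label) |>
    dplyr::summarise(log_evidence = mean(.data$log_evidence),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$target_mu,
                                    y = .data$log_evidence,
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(mu[max] ~ "of target curve"),
                  y = "ln Z", colour = "prior") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
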