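#' Plot simulated-versus-recovered parameters
#'
#' Scatter of generating against recovered values, one facet per parameter,
#' with the identity line and the recovery correlation in the facet label.
#'
#' @param object a [recovery_report][run_parameter_recovery].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  s <- tidy(object)
  est <- dplyr::left_join(object$estimates, s, by = "term") |>
    dplyr::mutate(panel = sprintf("%s (r = %.3f)", .data$term, .data$r))
  ggplot2::ggplot(est, ggplot2::aes(.data$true, .data$recovered)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(
      x = "generating value", y = "recovered value",
      title = sprintf("Parameter recovery, model %d (%d simulations)",
                      object$model, object$n_sims)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a model-confusion matrix
#'
#' @param object a [confusion_report][run_confusion].
#' @param ... unused.
#' @return a ggplot heat map of exceedance probabilities.
#' @export
autoplot.confusion_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$candidate, .data$generator,
                                  fill = .data$ep)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ep)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "selected model", y = "generating model",
                  fill = "exceedance\nprobability") +
    ggplot2::theme_minimal()
}

#' Plot hierarchical model-comparison summaries
#'
#' Model frequencies and protected exceedance probabilities side by side.
#'
#' @param object an [hbi_fit][fit_hierarchical].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hbi_fit <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("frequency", "pxp"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$model), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "model", y = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a posterior-predictive check
#'
#' The observed cohort-mean role-estimate trajectory over the
#' posterior-predictive mean and its pointwise credible band.
#'
#' @param object a [ppc_report][run_ppc].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ppc_report <- function(object, ...) {
  ggplot2::ggplot(object$by_trial, ggplot2::aes(.data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predictive_mean),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.9) +
    ggplot2::labs(
      x = "trial", y = "mean role estimate",
      title = sprintf("Posterior-predictive check, model %d (coverage %.0f%%)",
                      object$model, 100 * object$coverage)
    ) +
    ggplot2::theme_minimal()
}
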