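#' Learning-curve plot for a fitted network
#'
#' @param object A `wta_fit` or `deep_fit`.
#' @param ... Unused.
#' @return A ggplot object: running training accuracy over presentations.
#' @method autoplot wta_fit
#' @export
autoplot.wta_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$iteration, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "presented samples", y = "running accuracy",
                  title = sprintf("Synaptic sampling (%s noise)",
                                  if (object$config$noise_on) "with"
                                  else "without")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wta_fit
#' @method autoplot deep_fit
#' @export
autoplot.deep_fit <- autoplot.wta_fit

#' Accuracy comparison plot for a paired noise comparison
#'
#' @param object A `noise_comparison`.
#' @param ... Unused.
#' @return A ggplot object: mean test and learning accuracy per condition
#'   with per-run points.
#' @method autoplot noise_comparison
#' @export
autoplot.noise_comparison <- function(object, ...) {
  m <- tidyr::pivot_longer(object$manifest,
                           cols = c("learn_accuracy", "test_accuracy"),
                           names_to = "phase", values_to = "accuracy")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$condition, y = .data$accuracy,
                                  fill = .data$condition)) +
    ggplot2::stat_summary(fun = mean, geom = "col", width = 0.6) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Spike raster plot
#'
#' @param spikes Spike tibble (e.g. from [poisson_spikes()] or
#'   [export_raster()]).
#' @return A ggplot object: one point per spike.
#' @export
plot_raster <- function(spikes) {
  ggplot2::ggplot(spikes, ggplot2::aes(x = .data$time_ms,
                                       y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
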