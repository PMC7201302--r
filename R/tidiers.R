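#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the learning curve of a fitted network
#'
#' @param x A `wta_fit` or `deep_fit`.
#' @param ... Unused.
#' @return Tibble with `iteration` and running `accuracy`.
#' @method tidy wta_fit
#' @export
tidy.wta_fit <- function(x, ...) x$curve

#' @rdname tidy.wta_fit
#' @method tidy deep_fit
#' @export
tidy.deep_fit <- function(x, ...) x$curve

#' One-row summary of a fitted network
#'
#' @param x A `wta_fit` or `deep_fit`.
#' @param ... Unused.
#' @return One-row tibble with sizes, noise condition and the final
#'   running accuracy.
#' @method glance wta_fit
#' @export
glance.wta_fit <- function(x, ...) {
  tibble::tibble(K = x$K, I = x$bank$n_neurons,
                 noise_on = x$config$noise_on, b = x$config$b,
                 final_accuracy = x$final_accuracy,
                 n_snapshots = length(x$snapshots), seed = x$seed)
}

#' @rdname glance.wta_fit
#' @method glance deep_fit
#' @export
glance.deep_fit <- function(x, ...) {
  tibble::tibble(K = x$K, J = x$J, I = x$bank$n_neurons,
                 noise_on = x$config$noise_on, b = x$config$b,
                 beta = x$beta, final_accuracy = x$final_accuracy,
                 n_snapshots = length(x$snapshots), seed = x$seed)
}

#' Tidy a paired noise comparison
#'
#' @param x A `noise_comparison`.
#' @param ... Unused.
#' @return The per-run manifest tibble (`run`, `seed`, `condition`,
#'   `learn_accuracy`, `test_accuracy`).
#' @method tidy noise_comparison
#' @export
tidy.noise_comparison <- function(x, ...) x$manifest

#' Condition-level summary of a paired noise comparison
#'
#' @param x A `noise_comparison`.
#' @param ... Unused.
#' @return One-row tibble with per-condition means and standard deviations
#'   of learning and test accuracy, and the with-minus-without gains.
#' @method glance noise_comparison
#' @export
glance.noise_comparison <- function(x, ...) {
  m <- x$manifest
  agg <- function(cond, col) m[[col]][m$condition == cond]
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  tibble::tibble(
    layers = x$layers, n_runs = x$profile$n_runs,
    mean_learn_with = mean(agg("with_noise", "learn_accuracy")),
    mean_learn_without = mean(agg("without_noise", "learn_accuracy")),
    mean_test_with = mean(agg("with_noise", "test_accuracy")),
    mean_test_without = mean(agg("without_noise", "test_accuracy")),
    sd_test_with = sd0(agg("with_noise", "test_accuracy")),
    sd_test_without = sd0(agg("without_noise", "test_accuracy")),
    learn_gain = mean_learn_with - mean_learn_without,
    test_gain = mean_test_with - mean_test_without)
}

#' Tidy a Hessian-trace decomposition
#'
#' @param x A `hessian_trace`.
#' @param ... Unused.
#' @return One-row tibble with `A`, `B`, `C`, `total` and `certified`.
#' @method tidy hessian_trace
#' @export
tidy.hessian_trace <- function(x, ...) {
  tibble::tibble(A = x$A, B = x$B, C = x$C, total = x$total,
                 certified = x$certified)
}

#' Tidy a strict-saddle report
#'
#' @param x A `saddle_report`.
#' @param ... Unused.
#' @return The per-run counts tibble.
#' @method tidy saddle_report
#' @export
tidy.saddle_report <- function(x, ...) x$per_run

#' @rdname tidy.saddle_report
#' @method glance saddle_report
#' @export
glance.saddle_report <- function(x, ...) x$summary
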