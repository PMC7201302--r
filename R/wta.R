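#' Membrane potentials of the output layer
#'
#' `u_k(t) = sum_i w_ki x_i(t)`: each output neuron integrates the EPSP
#' traces of its afferents, weighted by the synaptic weights.  There is no
#' separate leak term; the traces themselves carry the temporal filtering.
#'
#' @param x Trace matrix (`n_bins` x `I`) from [epsp_trace()].
#' @param w Weight matrix (`K` x `I`), non-negative.
#' @return Potential matrix (`n_bins` x `K`).
#' @export
membrane_potentials <- function(x, w) {
  if (ncol(x) != ncol(w))
    stop("trace has ", ncol(x), " neurons but weight matrix has ", ncol(w),
         " columns", call. = FALSE)
  x %*% t(w)
}

#' Winner-take-all instantaneous firing rates
#'
#' Firing rates depend exponentially on the membrane potential; lateral
#' inhibition is modelled as divisive normalisation under a shared rate
#' budget, so at every time bin
#' `rho_k(t) = R_total * exp(u_k(t)) / sum_l exp(u_l(t))`.
#' The softmax is computed with per-bin max subtraction, making the result
#' invariant to adding a constant to all potentials.
#'
#' @param u Potential matrix (`n_bins` x `K`).
#' @param R_total Shared rate budget (Hz).
#' @return Rate matrix (`n_bins` x `K`); every row sums to `R_total`.
#' @export
wta_rates <- function(u, R_total = 100) {
  stopifnot(R_total >= 0)
  mx <- apply(u, 1L, max)
  e <- exp(u - mx)
  R_total * e / rowSums(e)
}

#' Sample the output spike pattern of the WTA circuit
#'
#' At most one output neuron spikes per time bin: with probability
#' `1 - R_total * dt` the bin is silent, otherwise the spiking neuron is
#' drawn from the categorical distribution proportional to `rho_k(t)`.
#'
#' @param rho Rate matrix (`n_bins` x `K`) from [wta_rates()].
#' @param dt_ms Bin width (ms).
#' @param seed Optional seed (otherwise the global RNG stream is used).
#' @return An object of class `wta_output`: list with `spikes` (tibble
#'   `neuron`, `time_ms`), `counts` (length-`K` spike counts), `s_bar`
#'   (normalised counts, all zero when no spike occurred), `label`
#'   (predicted 0-based label) and window metadata.
#' @export
sample_output_spikes <- function(rho, dt_ms = 1, seed = NULL) {
  if (any(rho < 0)) stop("negative rate", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_bins <- nrow(rho)
  K <- ncol(rho)
  tot <- rowSums(rho)
  p_spike <- pmin(tot * dt_ms / 1000, 1)
  spike_bin <- stats::runif(n_bins) < p_spike
  neuron <- integer(0)
  times <- numeric(0)
  if (any(spike_bin)) {
    rows <- which(spike_bin)
    pm <- rho[rows, , drop = FALSE] / tot[rows]
    cum <- t(apply(pm, 1L, cumsum))
    u <- stats::runif(length(rows))
    neuron <- as.integer(rowSums(u > cum) + 1L)
    times <- (rows - 1) * dt_ms
  }
  counts <- tabulate(neuron, nbins = K)
  s_bar <- counts / max(1L, sum(counts))
  spikes <- tibble::tibble(neuron = neuron, time_ms = times)
  attr(spikes, "T_ms") <- n_bins * dt_ms
  attr(spikes, "dt_ms") <- dt_ms
  attr(spikes, "n_neurons") <- K
  structure(list(spikes = spikes, counts = counts, s_bar = s_bar,
                 label = predict_label(counts), T_ms = n_bins * dt_ms,
                 dt_ms = dt_ms),
            class = "wta_output")
}

#' @export
print.wta_output <- function(x, ...) {
  cat(sprintf("<wta_output: %d spikes over %g ms, predicted label %d>\n",
              sum(x$counts), x$T_ms, x$label))
  invisible(x)
}

#' Predicted class label from output spike counts
#'
#' The neuron that spikes most indicates the label; ties (including the
#' all-silent case) are broken towards the lowest neuron index.
#'
#' @param counts Integer vector of per-neuron spike counts, or a
#'   `wta_output`.
#' @return 0-based integer label.
#' @export
predict_label <- function(counts) {
  if (inherits(counts, "wta_output")) counts <- counts$counts
  as.integer(which.max(counts) - 1L)
}
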