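#' Forward pass through a hidden spiking layer
#'
#' Hidden potentials are the weighted sums of the input traces.  The
#' hidden layer is organised as several parallel WTA groups (a standard
#' cortical-microcircuit motif): neurons are partitioned into groups of
#' `group_size`, each group competes under its own softmax rate budget
#' `R_hidden` and emits at most one spike per time bin.  The grouped
#' arrangement keeps the hidden population code dense enough that its
#' filtered traces drive the next layer on the same scale as the input
#' traces drive the first.  Hidden spikes are filtered by the EPSP kernel
#' to produce the traces seen by the next layer.
#'
#' @param x Input trace matrix (`n_bins` x `I`).
#' @param state1 First-layer [synapse_state()] (`J` x `I`).
#' @param cm Convolution operator from `conv_matrix()` (recomputed when
#'   `NULL`).
#' @param R_hidden Rate budget per WTA group (Hz).
#' @param dt_ms Bin width (ms).
#' @param kernel EPSP kernel (used when `cm` is `NULL`).
#' @param group_size Number of hidden neurons per WTA group (the last
#'   group may be smaller).
#' @param keep_spikes If `TRUE`, also return the hidden spike tibble
#'   (skipped by default in the training hot path).
#' @return List with `y` (hidden trace matrix `n_bins` x `J`), `ybar`
#'   (time-averaged hidden traces), `counts` (hidden spike counts) and
#'   `spikes`.
#' @export
hidden_forward <- function(x, state1, cm = NULL, R_hidden = 200, dt_ms = 1,
                           kernel = epsp_kernel(dt_ms = dt_ms),
                           group_size = 5L, keep_spikes = FALSE) {
  J <- nrow(state1$theta)
  if (ncol(x) != ncol(state1$theta))
    stop("input traces have ", ncol(x), " neurons but first layer expects ",
         ncol(state1$theta), call. = FALSE)
  u <- x %*% t(state1$w)
  n_bins <- nrow(x)
  gs <- as.integer(group_size)
  G <- ceiling(J / gs)
  # pad to a full group grid; padded columns never win (prob 0)
  if (G * gs > J) u <- cbind(u, matrix(-Inf, n_bins, G * gs - J))
  # within-group softmax, vectorised over all groups at once
  slice <- function(k) u[, seq(k, G * gs, by = gs), drop = FALSE]
  mx <- slice(1)
  for (k in 2:gs) mx <- pmax(mx, slice(k))
  es <- vector("list", gs)
  tot <- matrix(0, n_bins, G)
  for (k in seq_len(gs)) {
    es[[k]] <- exp(slice(k) - mx)
    tot <- tot + es[[k]]
  }
  # one categorical draw per (bin, group) on spike bins
  spike_bin <- matrix(stats::runif(n_bins * G), n_bins, G) <
    min(R_hidden * dt_ms / 1000, 1)
  uu <- matrix(stats::runif(n_bins * G), n_bins, G)
  cum <- matrix(0, n_bins, G)
  winner <- matrix(1L, n_bins, G)
  decided <- matrix(FALSE, n_bins, G)
  for (k in seq_len(gs)) {
    cum <- cum + es[[k]] / tot
    hit <- !decided & (uu <= cum)
    winner[hit] <- k
    decided <- decided | hit
  }
  winner[!decided] <- gs   # numerical guard: cum may end at 1 - eps
  s_mat <- matrix(0, n_bins, G * gs)
  idx <- which(spike_bin, arr.ind = TRUE)
  if (nrow(idx)) {
    col <- (idx[, 2L] - 1L) * gs + winner[idx]
    keep <- col <= J
    s_mat[cbind(idx[keep, 1L], col[keep])] <- 1
  }
  s_mat <- s_mat[, seq_len(J), drop = FALSE]
  counts <- as.integer(colSums(s_mat))
  if (is.null(cm)) cm <- conv_matrix(n_bins, kernel)
  y <- cm %*% s_mat
  list(y = y, ybar = colMeans(y), counts = counts,
       spikes = if (keep_spikes) matrix_to_spikes(s_mat, dt_ms))
}

#' Output-layer update of the deep network
#'
#' Identical in functional form to the two-layer sampling step, with the
#' hidden traces playing the role of the inputs.  Returns both the updated
#' state and the applied increment `dtheta`, which the hidden-layer
#' back-propagation rule consumes.
#'
#' @param state2 Output-layer [synapse_state()].
#' @param stats Per-sample statistics list (`xbar` = hidden trace means,
#'   `s_bar`, `h`).
#' @param config A [plasticity_config()].
#' @return List with `state` (updated) and `dtheta` (`K` x `J` increment,
#'   prior + likelihood + noise, after clipping).
#' @export
output_layer_update <- function(state2, stats, config) {
  new_state <- sampling_step(state2, stats, config)
  list(state = new_state, dtheta = new_state$theta - state2$theta)
}

#' Hidden-layer back-propagation update
#'
#' The first-layer increment is assembled from the output-layer increments
#' of the neuron that actually fired most (`k`) and the desired neuron
#' (`m`):
#' `dtheta_ji = (beta / alpha) * xbar_i * (dtheta_L[k, j] + dtheta_L[m, j])`.
#' Stochasticity reaches the hidden layer through `dtheta_L`.
#'
#' @param state1 First-layer [synapse_state()].
#' @param xbar Time-averaged input traces (length `I`).
#' @param dtheta_L Output-layer increment (`K` x `J`).
#' @param k 0-based index of the output neuron that fired most.
#' @param m 0-based index of the desired output neuron.
#' @param beta Hidden-update scale; `beta = alpha` gives unit gain.
#' @param alpha Rate-scale constant.
#' @param theta_clip Clipping range applied after the update.
#' @return List with `state` (updated) and `dtheta` (`J` x `I` increment
#'   before clipping).
#' @export
hidden_layer_update <- function(state1, xbar, dtheta_L, k, m, beta, alpha,
                                theta_clip = c(-10, 8)) {
  K <- nrow(dtheta_L)
  if (k < 0 || k >= K || m < 0 || m >= K)
    stop("invalid output neuron index (k=", k, ", m=", m, ")", call. = FALSE)
  v <- dtheta_L[k + 1L, ] + dtheta_L[m + 1L, ]          # length J
  dtheta <- (beta / alpha) * outer(v, xbar)              # J x I
  theta <- state1$theta + dtheta
  theta <- pmin(pmax(theta, theta_clip[1]), theta_clip[2])
  list(state = synapse_state(theta, state1$theta0), dtheta = dtheta)
}

#' Train a three-layer noisy spiking network
#'
#' Input -> hidden -> output, with the sampling rule on the output layer
#' and the back-propagation rule on the hidden layer, applied sequentially
#' for every presented sample.
#'
#' @param samples Dataset tibble.
#' @param bank Input [tuning_bank()].
#' @param config A [plasticity_config()] (shared by both layers).
#' @param J Hidden-layer size.
#' @param K Number of output neurons.
#' @param beta Hidden-update scale of the back-propagation rule.  The
#'   default 0 freezes the first layer, making the hidden layer a fixed
#'   random spiking projection; at the reduced problem sizes used here
#'   any positive `beta` drives the first layer into saturation within
#'   the schedule (the rank-one updates of the rule have no
#'   weight-dependent self-limitation), which collapses the hidden code.
#'   `beta = config$alpha` gives the unit-gain back-propagation variant.
#' @param R_hidden,R_total Hidden (per WTA group) and output rate budgets
#'   (Hz).
#' @param group_size Hidden neurons per WTA group.
#' @param T_ms,dt_ms Window and bin width (ms).
#' @param kernel EPSP kernel.
#' @param acc_interval,snapshot_at,seed As in [train_wta()].
#' @return Object of class `deep_fit` with `layer1`, `layer2`, learning
#'   `curve`, `snapshots` (list of two-layer states) and run settings.
#' @export
train_deep <- function(samples, bank, config = plasticity_config(),
                       J = 100, K = 10, beta = NULL, R_hidden = 200,
                       group_size = 5L, R_total = 100, T_ms = 200, dt_ms = 1,
                       kernel = epsp_kernel(dt_ms = dt_ms),
                       acc_interval = 100, snapshot_at = integer(0),
                       seed = 1L) {
  if (!nrow(samples)) stop("empty training set", call. = FALSE)
  beta <- beta %||% 0
  set.seed(as.integer(seed))
  state1 <- init_synapses(J, bank$n_neurons, config)
  state2 <- init_synapses(K, J, config)
  cm <- conv_matrix(round(T_ms / dt_ms), kernel)
  feats <- feature_matrix(samples)
  labels <- samples$label
  n <- nrow(samples)
  correct <- logical(n)
  snapshots <- list()
  curve_it <- integer(0); curve_acc <- numeric(0)
  for (i in seq_len(n)) {
    rates <- firing_rates(feats[i, ], bank)
    s_in <- poisson_spike_matrix(rates, T_ms, dt_ms)
    x <- cm %*% s_in
    hf <- hidden_forward(x, state1, cm = cm, R_hidden = R_hidden,
                         dt_ms = dt_ms, group_size = group_size)
    u <- hf$y %*% t(state2$w)
    rho <- wta_rates(u, R_total)
    out <- sample_output_spikes(rho, dt_ms)
    correct[i] <- out$label == labels[i]
    st <- list(xbar = hf$ybar, s_bar = out$s_bar, h = one_hot(labels[i], K))
    upd <- output_layer_update(state2, st, config)
    state2 <- upd$state
    if (beta != 0) {
      hu <- hidden_layer_update(state1, colMeans(x), upd$dtheta,
                                out$label, labels[i], beta, config$alpha,
                                config$theta_clip)
      state1 <- hu$state
    }
    if (i %in% snapshot_at)
      snapshots[[as.character(i)]] <- list(layer1 = state1, layer2 = state2)
    if (i %% acc_interval == 0L || i == n) {
      lo <- max(1L, i - acc_interval + 1L)
      curve_it <- c(curve_it, i)
      curve_acc <- c(curve_acc, mean(correct[lo:i]))
    }
  }
  structure(list(layer1 = state1, layer2 = state2,
                 curve = tibble::tibble(iteration = curve_it,
                                        accuracy = curve_acc),
                 snapshots = snapshots, config = config, bank = bank,
                 kernel = kernel, J = J, K = K, beta = beta,
                 R_hidden = R_hidden, group_size = group_size,
                 R_total = R_total, T_ms = T_ms,
                 dt_ms = dt_ms, seed = seed,
                 final_accuracy = mean(correct[max(1, n - 499):n])),
            class = "deep_fit")
}

#' @export
print.deep_fit <- function(x, ...) {
  cat(sprintf(
    "<deep_fit: I=%d -> J=%d -> K=%d, noise %s, final running accuracy %.3f>\n",
    x$bank$n_neurons, x$J, x$K, if (x$config$noise_on) "on" else "off",
    x$final_accuracy))
  invisible(x)
}

#' Accuracy of a trained three-layer network
#'
#' @param samples Dataset tibble.
#' @param fit A `deep_fit`.
#' @param seed Integer evaluation seed (per-sample seeding, order
#'   invariant).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_deep <- function(samples, fit, seed = 1L) {
  if (!nrow(samples)) stop("empty evaluation set", call. = FALSE)
  cm <- conv_matrix(round(fit$T_ms / fit$dt_ms), fit$kernel)
  feats <- feature_matrix(samples)
  ids <- samples$sample_id %||% seq_len(nrow(samples))
  ok <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    set.seed(as.integer((as.numeric(seed) * 97 + ids[i] * 1000003) %%
                          2147483647))
    rates <- firing_rates(feats[i, ], fit$bank)
    s_in <- poisson_spike_matrix(rates, fit$T_ms, fit$dt_ms)
    x <- cm %*% s_in
    hf <- hidden_forward(x, fit$layer1, cm = cm, R_hidden = fit$R_hidden,
                         dt_ms = fit$dt_ms,
                         group_size = fit$group_size %||% 5L)
    u <- hf$y %*% t(fit$layer2$w)
    out <- sample_output_spikes(wta_rates(u, fit$R_total), fit$dt_ms)
    ok[i] <- out$label == samples$label[i]
  }
  mean(ok)
}
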