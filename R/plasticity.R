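#' Configuration for the synaptic-sampling plasticity rule
#'
#' Collects every scalar of the learning rule and its integration scheme.
#' The parameter update applied after each 200-ms presentation is
#' `theta <- theta + b * dt_update * (prior_drift + n_eff * stdp_drift + xi)`
#' where `xi` is the weight-dependent noise increment (zero when
#' `noise_on = FALSE`).  Under `noise_scaling = "wiener"` the noise instead
#' enters as `b * sqrt(dt_update) * xi`.
#'
#' @param N Sample-count constant in the likelihood and noise scaling.
#' @param alpha Rate-scale constant of the likelihood model (default
#'   `exp(-6)`).
#' @param b Learning rate.
#' @param mu,sigma Mean and standard deviation of the Gaussian prior over
#'   `theta`.
#' @param theta0 Offset of the exponential parameter-to-weight mapping
#'   `w = exp(theta - theta0)`.
#' @param dt_update Effective step length per applied update
#'   (dimensionless; one presentation = one step).
#' @param noise_on Whether the stochastic term is applied.
#' @param noise_param_is_std Interpretation of the noise scale
#'   `N * alpha * exp(w)`.  The default `FALSE` reads it as a variance,
#'   matching the moment structure of the underlying spike-count model (a
#'   sum of `N` Poisson draws has mean and *variance* `N * alpha * exp(w)`,
#'   and its normal approximation is written with that same second
#'   argument).  Set `TRUE` to read it as a standard deviation.
#' @param noise_scaling `"drift"` (noise at the same order as the drift) or
#'   `"wiener"` (square-root step scaling).
#' @param stdp_mode `"aggregated"` (one update from per-sample averaged
#'   statistics) or `"per_bin"` (sum over time bins).
#' @param rho_tgt Teaching rate (Hz) used by the per-bin mode for the
#'   desired neuron; defaults to the WTA rate budget at train time.
#' @param n_eff Likelihood scaling applied to the STDP drift; defaults to
#'   `N`.
#' @param theta_clip Length-2 numeric: `theta` is clipped to this range
#'   after every update so that `exp(exp(theta - theta0))` stays finite
#'   under large noise excursions.
#' @return An object of class `plasticity_config`.
#' @export
plasticity_config <- function(N = 1000, alpha = exp(-6), b = 1e-4,
                              mu = 0, sigma = 1, theta0 = 3,
                              dt_update = 1, noise_on = TRUE,
                              noise_param_is_std = FALSE,
                              noise_scaling = c("drift", "wiener"),
                              stdp_mode = c("aggregated", "per_bin"),
                              rho_tgt = NULL, n_eff = N,
                              theta_clip = c(-10, 8)) {
  noise_scaling <- match.arg(noise_scaling)
  stdp_mode <- match.arg(stdp_mode)
  stopifnot(sigma > 0, b >= 0, alpha > 0, N >= 1,
            length(theta_clip) == 2L, theta_clip[1] < theta_clip[2])
  structure(list(N = N, alpha = alpha, b = b, mu = mu, sigma = sigma,
                 theta0 = theta0, dt_update = dt_update,
                 noise_on = noise_on,
                 noise_param_is_std = noise_param_is_std,
                 noise_scaling = noise_scaling, stdp_mode = stdp_mode,
                 rho_tgt = rho_tgt, n_eff = n_eff,
                 theta_clip = theta_clip),
            class = "plasticity_config")
}

#' @export
print.plasticity_config <- function(x, ...) {
  cat(sprintf(paste0("<plasticity_config: N=%g, alpha=%.4g, b=%g, ",
                     "prior N(%g, %g^2), theta0=%g, noise %s (%s)>\n"),
              x$N, x$alpha, x$b, x$mu, x$sigma, x$theta0,
              if (x$noise_on) "on" else "off", x$noise_scaling))
  invisible(x)
}

#' Synaptic weights from log-domain parameters
#'
#' `w_ki = exp(theta_ki - theta0)`; strictly positive and strictly
#' increasing in `theta`.
#'
#' @param theta Parameter matrix (`K` x `I`).
#' @param theta0 Scalar offset.
#' @return Weight matrix of the same shape.
#' @export
weights_from_params <- function(theta, theta0) {
  exp(theta - theta0)
}

#' Initialise a synapse state from the prior
#'
#' `theta` entries are drawn i.i.d. from the prior `N(mu, sigma^2)`.
#'
#' @param K,I Output and input layer sizes.
#' @param config A [plasticity_config()].
#' @param seed Optional seed (otherwise the global RNG stream is used).
#' @return Object of class `synapse_state`: list with `theta`, `theta0`,
#'   and the derived weight matrix `w`.
#' @export
init_synapses <- function(K, I, config = plasticity_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  theta <- matrix(stats::rnorm(K * I, config$mu, config$sigma), K, I)
  synapse_state(theta, config$theta0)
}

#' @rdname init_synapses
#' @param theta Parameter matrix.
#' @param theta0 Offset scalar.
#' @export
synapse_state <- function(theta, theta0) {
  structure(list(theta = theta, theta0 = theta0,
                 w = weights_from_params(theta, theta0)),
            class = "synapse_state")
}

#' @export
print.synapse_state <- function(x, ...) {
  cat(sprintf("<synapse_state: %d x %d, theta0=%g, mean w=%.4g>\n",
              nrow(x$theta), ncol(x$theta), x$theta0, mean(x$w)))
  invisible(x)
}

#' Prior drift of the sampling rule
#'
#' The Gaussian prior over `theta` contributes `(mu - theta) / sigma^2`
#' elementwise, a constant pull towards the prior mean.
#'
#' @param theta Parameter matrix.
#' @param mu Prior mean.
#' @param sigma Prior standard deviation.
#' @return Drift matrix of the same shape as `theta`.
#' @export
prior_drift <- function(theta, mu, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  (mu - theta) / sigma^2
}

#' STDP-like likelihood drift (aggregated form)
#'
#' One presented sample contributes
#' `drift_ki = w_ki * (xbar_i - alpha * exp(w_ki)) * (h_k - s_bar_k)`.
#' The first factor is the simplified STDP window: potentiation when the
#' presynaptic trace exceeds the weight-dependent threshold
#' `alpha * exp(w)`, depression otherwise.  The second factor is the
#' supervision error: positive on the desired neuron's row when it
#' under-fires, negative on rows of neurons that fired in its place.
#'
#' @param xbar Time-averaged input traces (length `I`).
#' @param s_bar Normalised output spike counts (length `K`).
#' @param h One-hot label vector (length `K`).
#' @param w Weight matrix (`K` x `I`).
#' @param alpha Rate-scale constant.
#' @return Drift matrix (`K` x `I`).
#' @export
stdp_drift <- function(xbar, s_bar, h, w, alpha) {
  if (length(xbar) != ncol(w) || length(s_bar) != nrow(w) ||
      length(h) != nrow(w))
    stop("shape mismatch in stdp_drift", call. = FALSE)
  err <- h - s_bar                       # K
  w * (outer(err, xbar) - alpha * exp(w) * err)
}

# per-bin STDP drift: sum over bins of
#   w_ki (x_i(t) - alpha e^w) (h_k rho_tgt dt - s_k(t))
stdp_drift_bins <- function(x, s_mat, h, w, alpha, rho_tgt, dt_ms) {
  a <- outer(rep(1, nrow(x)), h * rho_tgt * dt_ms / 1000) - s_mat  # T x K
  w * (crossprod(a, x) - alpha * exp(w) * colSums(a))
}

#' Weight-dependent noise increment
#'
#' Draws `xi_ki ~ Normal(0, scale_ki)` with `scale_ki = N * alpha *
#' exp(w_ki)`, independent across synapses.  The scale is read as the
#' variance by default (see [plasticity_config()]), so larger weights —
#' larger spines — fluctuate more; this is the structured noise that
#' distinguishes the rule from constant-scale Brownian perturbations.
#'
#' @param w Weight matrix.
#' @param config A [plasticity_config()].
#' @param seed Optional seed (otherwise the global RNG stream is used).
#' @return Noise matrix of the same shape as `w`; all zero when
#'   `config$noise_on` is `FALSE`.
#' @export
noise_increment <- function(w, config, seed = NULL) {
  if (!config$noise_on) return(array(0, dim(w)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- config$N * config$alpha * exp(w)
  if (!config$noise_param_is_std) s <- sqrt(s)   # variance reading
  matrix(stats::rnorm(length(w), 0, s), nrow(w), ncol(w))
}

#' One synaptic-sampling update
#'
#' Applies the Euler step of the sampling rule to a synapse state given
#' the statistics of one presented sample.  With `stats = NULL` the
#' likelihood term is omitted (prior and noise only), which is useful for
#' studying the prior dynamics in isolation.
#'
#' @param state A [synapse_state()].
#' @param stats For the aggregated mode, a list with `xbar`, `s_bar` and
#'   one-hot `h`; for the per-bin mode additionally `x` (trace matrix) and
#'   `s_mat` (output spike bin matrix).  `NULL` disables the likelihood
#'   term.
#' @param config A [plasticity_config()].
#' @return The updated `synapse_state`.
#' @export
sampling_step <- function(state, stats, config) {
  theta <- state$theta
  drift <- prior_drift(theta, config$mu, config$sigma)
  if (!is.null(stats)) {
    lik <- if (config$stdp_mode == "per_bin") {
      stdp_drift_bins(stats$x, stats$s_mat, stats$h, state$w, config$alpha,
                      stats$rho_tgt %||% config$rho_tgt %||% 100,
                      stats$dt_ms %||% 1)
    } else {
      stdp_drift(stats$xbar, stats$s_bar, stats$h, state$w, config$alpha)
    }
    drift <- drift + config$n_eff * lik
  }
  step <- config$b * config$dt_update * drift
  if (config$noise_on) {
    xi <- noise_increment(state$w, config)
    step <- step + if (config$noise_scaling == "wiener")
      config$b * sqrt(config$dt_update) * xi
    else config$b * config$dt_update * xi
  }
  theta <- theta + step
  bad <- which(!is.finite(theta))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(theta))
    stop(sprintf("non-finite update at synapse (k=%d, i=%d)", rc[1], rc[2]),
         call. = FALSE)
  }
  theta <- pmin(pmax(theta, config$theta_clip[1]), config$theta_clip[2])
  synapse_state(theta, state$theta0)
}

# one-hot encoding of a 0-based label
one_hot <- function(label, K) {
  h <- numeric(K)
  h[label + 1L] <- 1
  h
}

# Encode one stimulus and run the WTA forward pass under the current
# weights.  Consumes the global RNG stream.  Returns the per-sample
# statistics needed by the learning rule and diagnostics.
present_sample <- function(features, label, state, bank, cm, K,
                           R_total = 100, T_ms = 200, dt_ms = 1,
                           keep_bins = FALSE) {
  rates <- firing_rates(features, bank)
  s_in <- poisson_spike_matrix(rates, T_ms, dt_ms)
  x <- cm %*% s_in
  u <- x %*% t(state$w)
  rho <- wta_rates(u, R_total)
  out <- sample_output_spikes(rho, dt_ms)
  stats <- list(xbar = colMeans(x), s_bar = out$s_bar,
                h = one_hot(label, K), label_hat = out$label,
                counts = out$counts, rho_tgt = R_total, dt_ms = dt_ms)
  if (keep_bins) {
    stats$x <- x
    stats$s_mat <- spikes_to_matrix(out$spikes)
    stats$spikes <- out$spikes
  }
  stats
}

#' Train a two-layer WTA network by synaptic sampling
#'
#' Presents the training samples sequentially (one simulated 200-ms window
#' each), applies one sampling update per presentation, and records the
#' running training accuracy.  Parameter snapshots can be requested at
#' specific iterations for downstream saddle diagnostics.
#'
#' @param samples Dataset tibble (from [generate_dataset()]); presented in
#'   row order.
#' @param bank A [tuning_bank()] matching the feature dimensionality.
#' @param config A [plasticity_config()].
#' @param K Number of output neurons (classes).
#' @param R_total WTA rate budget (Hz).
#' @param T_ms,dt_ms Presentation window and bin width (ms).
#' @param kernel EPSP kernel.
#' @param state Optional initial [synapse_state()]; drawn from the prior
#'   when omitted.
#' @param acc_interval Running accuracy is recorded every this many
#'   presentations.
#' @param snapshot_at Integer iterations at which to store a copy of
#'   `theta` (default none).
#' @param seed Integer seed governing every random draw of the run.
#' @return Object of class `wta_fit`: list with the final `state`, the
#'   learning `curve` tibble (`iteration`, `accuracy`), `snapshots` (named
#'   list of `synapse_state`s), and the run settings.
#' @export
train_wta <- function(samples, bank, config = plasticity_config(), K = 10,
                      R_total = 100, T_ms = 200, dt_ms = 1,
                      kernel = epsp_kernel(dt_ms = dt_ms), state = NULL,
                      acc_interval = 100, snapshot_at = integer(0),
                      seed = 1L) {
  if (!nrow(samples)) stop("empty training set", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(state)) state <- init_synapses(K, bank$n_neurons, config)
  cm <- conv_matrix(round(T_ms / dt_ms), kernel)
  feats <- feature_matrix(samples)
  labels <- samples$label
  n <- nrow(samples)
  correct <- logical(n)
  keep_bins <- config$stdp_mode == "per_bin"
  snapshots <- list()
  curve_it <- integer(0); curve_acc <- numeric(0)
  for (i in seq_len(n)) {
    st <- present_sample(feats[i, ], labels[i], state, bank, cm, K,
                         R_total, T_ms, dt_ms, keep_bins = keep_bins)
    correct[i] <- st$label_hat == labels[i]
    state <- sampling_step(state, st, config)
    if (i %in% snapshot_at)
      snapshots[[as.character(i)]] <- state
    if (i %% acc_interval == 0L || i == n) {
      lo <- max(1L, i - acc_interval + 1L)
      curve_it <- c(curve_it, i)
      curve_acc <- c(curve_acc, mean(correct[lo:i]))
    }
  }
  structure(list(state = state,
                 curve = tibble::tibble(iteration = curve_it,
                                        accuracy = curve_acc),
                 snapshots = snapshots, config = config, bank = bank,
                 kernel = kernel, K = K, R_total = R_total, T_ms = T_ms,
                 dt_ms = dt_ms, seed = seed,
                 final_accuracy = mean(correct[max(1, n - 499):n])),
            class = "wta_fit")
}

#' @export
print.wta_fit <- function(x, ...) {
  cat(sprintf("<wta_fit: K=%d, I=%d, noise %s, final running accuracy %.3f>\n",
              x$K, x$bank$n_neurons, if (x$config$noise_on) "on" else "off",
              x$final_accuracy))
  invisible(x)
}

#' Classification accuracy of a trained state on a dataset
#'
#' Each sample is encoded and presented once with no learning; the
#' prediction is the output neuron with the most spikes.  Per-sample
#' randomness is seeded from `seed` and the sample's `sample_id`, so the
#' result does not depend on row order.
#'
#' @param samples Dataset tibble.
#' @param state A trained [synapse_state()] or a `wta_fit`.
#' @param bank Tuning bank (taken from the fit when `state` is a
#'   `wta_fit`).
#' @param K,R_total,T_ms,dt_ms,kernel Network settings (taken from the fit
#'   when available).
#' @param seed Integer evaluation seed.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(samples, state, bank = NULL, K = 10,
                              R_total = 100, T_ms = 200, dt_ms = 1,
                              kernel = epsp_kernel(dt_ms = dt_ms),
                              seed = 1L) {
  if (!nrow(samples)) stop("empty evaluation set", call. = FALSE)
  if (inherits(state, "wta_fit")) {
    fit <- state
    state <- fit$state; bank <- bank %||% fit$bank; K <- fit$K
    R_total <- fit$R_total; T_ms <- fit$T_ms; dt_ms <- fit$dt_ms
    kernel <- fit$kernel
  }
  cm <- conv_matrix(round(T_ms / dt_ms), kernel)
  feats <- feature_matrix(samples)
  ids <- samples$sample_id %||% seq_len(nrow(samples))
  ok <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    set.seed(as.integer((as.numeric(seed) * 97 + ids[i] * 1000003) %%
                          2147483647))
    st <- present_sample(feats[i, ], samples$label[i], state, bank, cm, K,
                         R_total, T_ms, dt_ms)
    ok[i] <- st$label_hat == samples$label[i]
  }
  mean(ok)
}
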