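#' Build a bank of Gaussian tuning-curve input neurons
#'
#' In tuning-curve mode each input neuron is assigned a preferred stimulus
#' coordinate (one of the feature dimensions, chosen uniformly) and a
#' preferred value on that coordinate, uniform over `center_range`; its
#' firing rate for a stimulus falls off as a Gaussian of the distance
#' between the stimulus value and the preferred value.  In pixel mode
#' neuron `i` reads feature `i` directly and fires at `r_max * v_i`.  A
#' constant background rate is added in both modes.
#'
#' The defaults are calibrated to the synthetic Gaussian-cluster task:
#' stimulus coordinates are approximately `N(0.5, 0.49^2)`, so preferred
#' values span `[-0.5, 1.5]` (the central ~95% of the stimulus mass) and
#' the tuning width is ~0.7 stimulus standard deviations.  This yields the
#' near-uniform spread of single-trial firing rates that makes the
#' population code informative.
#'
#' @param n_neurons Number of input neurons.
#' @param n_features Stimulus dimensionality.
#' @param sigma_tc Tuning-curve width (feature units).
#' @param center_range Length-2 numeric range from which preferred values
#'   are drawn uniformly.
#' @param r_max Peak rate above background (Hz).
#' @param r_bg Background rate (Hz); 5 Hz by default.
#' @param mode `"tuning"` (Gaussian tuning curves) or `"pixel"`
#'   (one neuron per feature, rate proportional to the value).
#' @param seed Seed for the random tuning-curve assignment.
#' @return An object of class `tuning_bank`.
#' @export
tuning_bank <- function(n_neurons, n_features = 3L, sigma_tc = 0.35,
                        r_max = 80, r_bg = 5, mode = c("tuning", "pixel"),
                        center_range = c(-0.5, 1.5), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_neurons >= 1, r_max >= 0, r_bg >= 0, sigma_tc > 0)
  n_neurons <- as.integer(n_neurons)
  if (mode == "pixel") {
    dim_index <- seq_len(n_neurons)
    center <- rep(NA_real_, n_neurons)
    if (n_features != n_neurons)
      n_features <- n_neurons
  } else {
    set.seed(as.integer(seed))
    dim_index <- sample.int(n_features, n_neurons, replace = TRUE)
    center <- stats::runif(n_neurons, center_range[1], center_range[2])
  }
  structure(list(n_neurons = n_neurons, n_features = as.integer(n_features),
                 dim_index = dim_index, center = center, sigma_tc = sigma_tc,
                 r_max = r_max, r_bg = r_bg, mode = mode),
            class = "tuning_bank")
}

#' @export
print.tuning_bank <- function(x, ...) {
  cat(sprintf("<tuning_bank: %d neurons, %d features, mode=%s, r_max=%g Hz, r_bg=%g Hz>\n",
              x$n_neurons, x$n_features, x$mode, x$r_max, x$r_bg))
  invisible(x)
}

#' Firing rates of the input layer for one stimulus
#'
#' Tuning-curve mode: `rate_i = r_max * exp(-(v[d_i] - c_i)^2 / (2 sigma^2))
#' + r_bg`.  Pixel mode: `rate_i = r_max * v_i + r_bg`.
#'
#' @param features Numeric feature vector (one stimulus).
#' @param bank A [tuning_bank()].
#' @return Numeric vector of rates in Hz, all `>= r_bg`.
#' @export
firing_rates <- function(features, bank) {
  stopifnot(inherits(bank, "tuning_bank"))
  if (bank$mode == "pixel") {
    if (length(features) != bank$n_neurons)
      stop("feature length ", length(features), " != n_neurons ",
           bank$n_neurons, call. = FALSE)
    return(bank$r_max * features + bank$r_bg)
  }
  if (length(features) < max(bank$dim_index))
    stop("feature length ", length(features),
         " incompatible with tuning bank", call. = FALSE)
  v <- features[bank$dim_index]
  bank$r_max * exp(-(v - bank$center)^2 / (2 * bank$sigma_tc^2)) + bank$r_bg
}

#' Double-exponential EPSP kernel
#'
#' `eps(s) = c * (exp(-s/tau_d) - exp(-s/tau_r))`, truncated at `trunc_ms`
#' and causal (zero at non-positive lags).  The default `"peak"`
#' normalisation scales the kernel to maximum 1, making traces
#' dimensionless with a single spike contributing a unit-height EPSP; the
#' time-averaged trace of a neuron firing at 80 Hz is then ~1, which puts
#' the likelihood fixed point `ln(xbar / alpha)` of the learning rule near
#' `w ~ 6` for strongly driven inputs.  `"area"` normalisation (unit
#' integral over the grid, traces in spikes/ms) is available.
#'
#' @param tau_r_ms,tau_d_ms Rise and decay time constants (ms).
#' @param trunc_ms Truncation length (ms).
#' @param dt_ms Time step (ms).
#' @param normalize `"peak"` (unit maximum, default) or `"area"` (unit
#'   integral).
#' @return Object of class `epsp_kernel`: a numeric vector of kernel values
#'   at lags `0, dt, 2 dt, ...` with attributes.
#' @export
epsp_kernel <- function(tau_r_ms = 1, tau_d_ms = 10, trunc_ms = 50,
                        dt_ms = 1, normalize = c("peak", "area")) {
  normalize <- match.arg(normalize)
  stopifnot(tau_r_ms > 0, tau_d_ms > tau_r_ms, trunc_ms > 0, dt_ms > 0)
  lags <- seq(0, trunc_ms, by = dt_ms)
  v <- exp(-lags / tau_d_ms) - exp(-lags / tau_r_ms)
  v <- if (normalize == "peak") v / max(v) else v / (sum(v) * dt_ms)
  structure(v, lags_ms = lags, dt_ms = dt_ms, normalize = normalize,
            class = "epsp_kernel")
}

#' Poisson spike trains for a vector of rates
#'
#' Spikes are drawn independently per time bin (width `dt_ms`) with
#' probability `min(rate * dt, 1)`; exact Poisson statistics are recovered
#' as `dt -> 0`.  Spike times are reported at the left edge of their bin.
#'
#' @param rates Non-negative rate vector (Hz), one entry per neuron.
#' @param T_ms Window length (ms); 200 ms by default.
#' @param dt_ms Bin width (ms).
#' @param seed Optional integer seed.
#' @return A tibble with columns `neuron` (1-based index) and `time_ms`,
#'   with attributes `T_ms`, `dt_ms` and `n_neurons`.
#' @export
poisson_spikes <- function(rates, T_ms = 200, dt_ms = 1, seed = NULL) {
  m <- poisson_spike_matrix(rates, T_ms, dt_ms, seed)
  matrix_to_spikes(m, dt_ms)
}

# fast path: T x I 0/1 matrix of spikes, consumes the global RNG unless
# seeded explicitly
poisson_spike_matrix <- function(rates, T_ms = 200, dt_ms = 1, seed = NULL) {
  if (any(rates < 0)) stop("negative firing rate", call. = FALSE)
  stopifnot(dt_ms > 0)
  n_bins <- round(T_ms / dt_ms)
  if (abs(n_bins * dt_ms - T_ms) > 1e-9)
    stop("T_ms must be a multiple of dt_ms", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- pmin(rates * dt_ms / 1000, 1)
  m <- matrix(stats::runif(n_bins * length(rates)), n_bins, length(rates))
  m <- (m < rep(p, each = n_bins)) * 1
  attr(m, "dt_ms") <- dt_ms
  m
}

# converters between the tidy spike representation and the bin matrix
matrix_to_spikes <- function(m, dt_ms = attr(m, "dt_ms") %||% 1) {
  idx <- which(m > 0, arr.ind = TRUE)
  out <- tibble::tibble(neuron = as.integer(idx[, 2L]),
                        time_ms = (idx[, 1L] - 1) * dt_ms)
  out <- dplyr::arrange(out, .data$neuron, .data$time_ms)
  attr(out, "T_ms") <- nrow(m) * dt_ms
  attr(out, "dt_ms") <- dt_ms
  attr(out, "n_neurons") <- ncol(m)
  out
}

spikes_to_matrix <- function(spikes, n_neurons = attr(spikes, "n_neurons"),
                             T_ms = attr(spikes, "T_ms"),
                             dt_ms = attr(spikes, "dt_ms") %||% 1) {
  n_bins <- round(T_ms / dt_ms)
  m <- matrix(0, n_bins, n_neurons)
  if (nrow(spikes))
    m[cbind(floor(spikes$time_ms / dt_ms) + 1L, spikes$neuron)] <- 1
  attr(m, "dt_ms") <- dt_ms
  m
}

#' EPSP traces from spike trains
#'
#' Convolves each neuron's spike train with the EPSP kernel:
#' `x_i(t) = sum_f eps(t - t_i^(f))`.  The trace is causal, non-negative
#' and linear in the spikes.
#'
#' @param spikes Spike tibble from [poisson_spikes()] (or a 0/1 bin matrix).
#' @param kernel An [epsp_kernel()].
#' @return A numeric matrix (`n_bins` x `n_neurons`) of dimensionless trace
#'   values.
#' @export
epsp_trace <- function(spikes, kernel = epsp_kernel()) {
  m <- if (is.matrix(spikes)) spikes else spikes_to_matrix(spikes)
  conv_matrix(nrow(m), kernel) %*% m
}

# lower-triangular banded convolution operator for a window of n_bins
conv_matrix <- function(n_bins, kernel) {
  kv <- as.numeric(kernel)
  L <- min(length(kv), n_bins)
  cm <- matrix(0, n_bins, n_bins)
  for (l in seq_len(L) - 1L)
    cm[cbind((1L + l):n_bins, 1L:(n_bins - l))] <- kv[l + 1L]
  cm
}

#' Time-averaged trace values
#'
#' @param x Trace matrix from [epsp_trace()].
#' @return Numeric vector: the mean of each neuron's trace over the window.
#' @export
mean_trace <- function(x) {
  if (!nrow(x)) stop("empty window", call. = FALSE)
  colMeans(x)
}

#' Write / read spike trains as two-column delimited text
#'
#' @param spikes Spike tibble.
#' @param path File path.
#' @param T_ms,n_neurons Window metadata used when reading back.
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()` a
#'   spike tibble.
#' @export
write_spikes <- function(spikes, path) {
  header <- sprintf("# T_ms=%g dt_ms=%g n_neurons=%d",
                    attr(spikes, "T_ms") %||% (max(spikes$time_ms, 0) + 1),
                    attr(spikes, "dt_ms") %||% 1,
                    attr(spikes, "n_neurons") %||% max(spikes$neuron, 1L))
  writeLines(c(header, "neuron,time_ms",
               sprintf("%d,%g", spikes$neuron, spikes$time_ms)), path)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  meta <- lines[1L]
  num <- function(key) as.numeric(sub(paste0(".*", key, "=([-0-9.eE+]+).*"),
                                      "\\1", meta))
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, ",", fixed = TRUE))
    out <- tibble::tibble(neuron = as.integer(parts[, 1L]),
                          time_ms = as.numeric(parts[, 2L]))
  } else {
    out <- tibble::tibble(neuron = integer(0), time_ms = numeric(0))
  }
  attr(out, "T_ms") <- num("T_ms")
  attr(out, "dt_ms") <- num("dt_ms")
  attr(out, "n_neurons") <- as.integer(num("n_neurons"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
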