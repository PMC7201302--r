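#' Hessian-trace decomposition of the learning objective
#'
#' The trace of the Hessian of the objective splits into three terms:
#' `A = -K * I / sigma^2` (prior curvature, always negative),
#' `B = sum_ki (theta_ki - mu) / sigma^2` (parameter displacement from the
#' prior mean), and
#' `C = sum_batch sum_k sum_i w_ki * alpha * exp(w_ki) * (S_k - h_k)`
#' (the misclassification-weighted likelihood curvature).  `S_k` defaults
#' to the normalised per-sample output count; a per-bin spike-count mode is
#' available via `s_total`.
#'
#' @param state A [synapse_state()].
#' @param batch List of per-sample statistics, each a list with `s_bar`
#'   (or `s_total` for the per-bin mode) and one-hot `h`.
#' @param sigma,mu Prior standard deviation and mean.
#' @param alpha Rate-scale constant.
#' @param mode `"aggregated"` uses `s_bar`; `"per_bin"` uses the raw spike
#'   counts `s_total`.
#' @return Object of class `hessian_trace`: list with `A`, `B`, `C`,
#'   `total` and `certified` (`TRUE` iff `A + B + C > 0`).
#' @export
hessian_trace_terms <- function(state, batch, sigma = 1, mu = 0,
                                alpha = exp(-6),
                                mode = c("aggregated", "per_bin")) {
  mode <- match.arg(mode)
  if (!length(batch)) stop("empty batch", call. = FALSE)
  K <- nrow(state$theta); I <- ncol(state$theta)
  A <- -K * I / sigma^2
  B <- sum(state$theta - mu) / sigma^2
  wexpw_row <- rowSums(state$w * alpha * exp(state$w))   # length K
  C <- 0
  for (st in batch) {
    s <- if (mode == "per_bin") st$s_total else st$s_bar
    C <- C + sum(wexpw_row * (s - st$h))
  }
  total <- A + B + C
  structure(list(A = A, B = B, C = C, total = total, certified = total > 0),
            class = "hessian_trace")
}

#' @export
print.hessian_trace <- function(x, ...) {
  cat(sprintf("<hessian_trace: A=%.4g, B=%.4g, C=%.4g, total=%.4g, %s>\n",
              x$A, x$B, x$C, x$total,
              if (x$certified) "certified strict saddle" else "not certified"))
  invisible(x)
}

#' Strict-saddle certificate
#'
#' `TRUE` iff the Hessian trace bound `A + B + C > 0` holds strictly, in
#' which case at least one eigenvalue of the Hessian is strictly positive
#' and the point admits a descent-enabling direction.
#'
#' @param terms A `hessian_trace` object, or a numeric vector `c(A, B, C)`.
#' @return Logical.
#' @export
strict_saddle_certified <- function(terms) {
  if (inherits(terms, "hessian_trace")) return(terms$total > 0)
  sum(terms) > 0
}

#' Count certified strict-saddle configurations over snapshots x inputs
#'
#' Evaluates the trace certificate for every (parameter snapshot, input)
#' pair, using the single input as the batch, and returns the number of
#' pairs for which the certificate holds.  The per-pair results are also
#' returned for inspection.
#'
#' @param snapshots Non-empty list of [synapse_state()]s (typically taken
#'   near convergence of training runs).
#' @param inputs Non-empty list of per-sample statistics (each with
#'   `s_bar`/`s_total` and `h`), pre-computed under the corresponding
#'   snapshot's weights (see [snapshot_input_stats()]).  When `inputs` is
#'   a list of such lists (one per snapshot) the i-th element is paired
#'   with the i-th snapshot; a flat list is reused for every snapshot.
#' @param sigma,mu,alpha,mode Passed to [hessian_trace_terms()].
#' @return Integer count with attribute `detail`, a tibble of per-pair
#'   certificates.
#' @export
count_certified <- function(snapshots, inputs, sigma = 1, mu = 0,
                            alpha = exp(-6),
                            mode = c("aggregated", "per_bin")) {
  mode <- match.arg(mode)
  if (!length(snapshots)) stop("no snapshots supplied", call. = FALSE)
  if (!length(inputs)) stop("no inputs supplied", call. = FALSE)
  per_snapshot <- !is.null(inputs[[1L]]) && is.null(inputs[[1L]]$h)
  rows <- list()
  for (s in seq_along(snapshots)) {
    ins <- if (per_snapshot) inputs[[s]] else inputs
    for (j in seq_along(ins)) {
      ht <- hessian_trace_terms(snapshots[[s]], list(ins[[j]]), sigma, mu,
                                alpha, mode)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(snapshot = s, input = j, A = ht$A, B = ht$B,
                       C = ht$C, total = ht$total, certified = ht$certified)
    }
  }
  detail <- dplyr::bind_rows(rows)
  structure(sum(detail$certified), detail = detail)
}

# Run the forward pass of a snapshot on a set of samples and collect the
# per-sample statistics needed by the certificate.  Traces can be supplied
# pre-computed (list with x, xbar per sample) to share encoding work
# across snapshots.
#' Forward-pass statistics of a snapshot over a set of inputs
#'
#' @param state A [synapse_state()].
#' @param samples Dataset tibble.
#' @param bank Tuning bank.
#' @param K,R_total,T_ms,dt_ms,kernel Network settings.
#' @param traces Optional pre-computed per-sample trace list (`x`, from
#'   [precompute_traces()]) so the Poisson encoding is shared across
#'   snapshots.
#' @param seed Evaluation seed.
#' @return List of per-sample statistics lists.
#' @export
snapshot_input_stats <- function(state, samples, bank, K = 10,
                                 R_total = 100, T_ms = 200, dt_ms = 1,
                                 kernel = epsp_kernel(dt_ms = dt_ms),
                                 traces = NULL, seed = 1L) {
  ids <- samples$sample_id %||% seq_len(nrow(samples))
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    set.seed(as.integer((as.numeric(seed) * 131 + ids[i] * 7919) %%
                          2147483647))
    x <- if (!is.null(traces)) traces[[i]] else {
      cm <- conv_matrix(round(T_ms / dt_ms), kernel)
      epsp_trace(poisson_spike_matrix(firing_rates(
        as.numeric(feature_matrix(samples[i, ])), bank), T_ms, dt_ms),
        kernel)
    }
    u <- x %*% t(state$w)
    res <- sample_output_spikes(wta_rates(u, R_total), dt_ms)
    out[[i]] <- list(s_bar = res$s_bar, s_total = res$counts,
                     h = one_hot(samples$label[i], K),
                     label_hat = res$label)
  }
  out
}

#' Pre-compute EPSP traces for a set of samples
#'
#' @param samples Dataset tibble.
#' @param bank Tuning bank.
#' @param T_ms,dt_ms,kernel Encoding settings.
#' @param seed Integer seed (per-sample, order invariant).
#' @return List of trace matrices, one per sample row.
#' @export
precompute_traces <- function(samples, bank, T_ms = 200, dt_ms = 1,
                              kernel = epsp_kernel(dt_ms = dt_ms),
                              seed = 1L) {
  cm <- conv_matrix(round(T_ms / dt_ms), kernel)
  feats <- feature_matrix(samples)
  ids <- samples$sample_id %||% seq_len(nrow(samples))
  lapply(seq_len(nrow(samples)), function(i) {
    set.seed(as.integer((as.numeric(seed) * 211 + ids[i] * 104729) %%
                          2147483647))
    cm %*% poisson_spike_matrix(firing_rates(feats[i, ], bank), T_ms, dt_ms)
  })
}

#' Reduction rate of certified strict-saddle counts
#'
#' `(S2 - S1) / S2`: the fractional decrease in certified strict-saddle
#' occurrences between the without-noise condition (`S2`) and the
#' with-noise condition (`S1`).
#'
#' @param S1 Certified count from noise-trained snapshots.
#' @param S2 Certified count from noiseless-trained snapshots; must be
#'   positive.
#' @param as_percent_string If `TRUE`, also return a percentage string
#'   rounded to two decimals as an attribute.
#' @return The fraction (may be negative when `S1 > S2`).
#' @export
reduction_rate <- function(S1, S2, as_percent_string = FALSE) {
  if (S2 <= 0) stop("`S2` must be positive", call. = FALSE)
  r <- (S2 - S1) / S2
  if (as_percent_string)
    attr(r, "percent") <- sprintf("%.2f%%", 100 * r)
  r
}

#' Moments of a sum of N Poisson draws with weight-dependent mean
#'
#' A sum of `N` independent Poisson(`alpha * exp(w)`) variables has mean
#' and variance both equal to `N * alpha * exp(w)`; for large `N` the sum
#' is approximately normal with these moments, which is the moment
#' structure underlying the weight-dependent noise scale.
#'
#' @param w Synaptic weight (scalar or vector).
#' @param N Number of summed draws.
#' @param alpha Rate-scale constant.
#' @return A tibble with columns `w`, `mean`, `variance`.
#' @export
poisson_sum_moments <- function(w, N = 1000, alpha = exp(-6)) {
  stopifnot(N >= 1)
  m <- N * alpha * exp(w)
  tibble::tibble(w = w, mean = m, variance = m)
}

#' Central probability mass of a normal distribution
#'
#' Probability that a normal variate falls within `k` standard deviations
#' of its mean: `2 * pnorm(k) - 1` (equivalently the error function at
#' `k / sqrt(2)`).
#'
#' @param k Number of standard deviations (`>= 0`).
#' @return Probability in `[0, 1]`.
#' @export
gaussian_central_mass <- function(k) {
  stopifnot(all(k >= 0))
  2 * stats::pnorm(k) - 1
}
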