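#' Synthetic-task experiment profiles
#'
#' The full profile mirrors the reference experiment (1,000 tuning-curve
#' input neurons, 14,400 training samples, 10 paired runs, hidden size 500
#' for the three-layer variant).  The reduced profile is the desk-scale
#' configuration used by the test suite and the acceptance script: 200
#' input neurons, 3,000 training samples, 1,000 test samples, 3 paired
#' runs, hidden size 100.
#'
#' @param scale `"reduced"` or `"full"`.
#' @return A named list of profile settings.
#' @export
synthesis_profile <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "full")
    list(scale = "full", n_classes = 10L, n_features = 3L, I = 1000L,
         n_train = 14400L, n_test = 1000L, n_runs = 10L, J = 500L,
         n_snapshots = 3L, n_saddle_inputs = 1000L, dt_update = 1,
         dt_update_deep = 1)
  else
    list(scale = "reduced", n_classes = 10L, n_features = 3L, I = 200L,
         n_train = 3000L, n_test = 1000L, n_runs = 3L, J = 100L,
         n_snapshots = 10L, n_saddle_inputs = 100L, dt_update = 4.8,
         dt_update_deep = 14.4)
}

#' Paired with-noise / without-noise comparison on the synthetic task
#'
#' For each run a fresh sensory environment (cluster parameters, dataset,
#' tuning bank) is generated from the run seed, then the network is
#' trained twice with matched seeds — once with the stochastic term, once
#' without — so the comparison isolates the noise term.  Test accuracy is
#' measured on a held-out set generated from the same clusters.
#'
#' @param profile A [synthesis_profile()].
#' @param config A [plasticity_config()], or `NULL` (default) to use the
#'   profile's Euler step (`dt_update` for two layers, `dt_update_deep`
#'   for three, so the reduced schedule covers the same integrated
#'   learning time as the corresponding full one).  The `noise_on` field
#'   is overridden per arm.
#' @param layers 2 (WTA only) or 3 (hidden layer + WTA).
#' @param seed Master integer seed.
#' @param snapshots If `TRUE`, tail parameter snapshots are stored for the
#'   saddle pipeline.
#' @param progress Print one line per completed arm.
#' @return Object of class `noise_comparison`: list with `manifest`
#'   (per-run tibble of learning and test accuracies), `runs` (per-run
#'   fits, test sets and banks), and the settings.
#' @export
run_comparison <- function(profile = synthesis_profile(), config = NULL,
                           layers = 2, seed = 1L, snapshots = TRUE,
                           progress = FALSE) {
  stopifnot(layers %in% c(2, 3))
  if (is.null(config))
    config <- plasticity_config(dt_update = if (layers == 3)
      profile$dt_update_deep else profile$dt_update)
  seed <- as.integer(seed)
  n <- profile$n_train
  snapshot_at <- if (snapshots)
    unique(round(seq(ceiling(2 * n / 3), n,
                     length.out = profile$n_snapshots)))
  else integer(0)
  runs <- list()
  rows <- list()
  for (r in seq_len(profile$n_runs)) {
    run_seed <- (seed * 1009L + r * 101L) %% 1000000L
    params <- sample_cluster_params(profile$n_classes, profile$n_features,
                                    seed = run_seed)
    train <- generate_dataset(params, n, seed = run_seed + 500000L)
    test <- generate_dataset(params, profile$n_test,
                             seed = run_seed + 700000L)
    bank <- tuning_bank(profile$I, profile$n_features,
                        seed = run_seed + 900000L)
    arm <- list()
    for (noise_on in c(TRUE, FALSE)) {
      cfg <- config
      cfg$noise_on <- noise_on
      fit <- if (layers == 2)
        train_wta(train, bank, cfg, K = profile$n_classes,
                  snapshot_at = snapshot_at, seed = run_seed)
      else
        train_deep(train, bank, cfg, J = profile$J,
                   K = profile$n_classes, snapshot_at = snapshot_at,
                   seed = run_seed)
      test_acc <- posterior_test_accuracy(fit, test, seed = run_seed + 1L)
      cond <- if (noise_on) "with_noise" else "without_noise"
      arm[[cond]] <- fit
      rows[[length(rows) + 1L]] <- tibble::tibble(
        run = r, seed = run_seed, condition = cond,
        learn_accuracy = fit$final_accuracy, test_accuracy = test_acc)
      if (progress)
        message(sprintf("run %d %s: learn %.3f, test %.3f", r, cond,
                        fit$final_accuracy, test_acc))
    }
    runs[[r]] <- list(with_noise = arm$with_noise,
                      without_noise = arm$without_noise,
                      test = test, params = params, bank = bank,
                      run_seed = run_seed)
  }
  structure(list(manifest = dplyr::bind_rows(rows), runs = runs,
                 profile = profile, config = config, layers = layers,
                 seed = seed),
            class = "noise_comparison")
}

#' Posterior-averaged test accuracy of a fitted network
#'
#' Synaptic sampling treats the parameters as samples from a posterior
#' distribution, so the test-phase performance of a run is estimated as
#' the mean accuracy over the last few stored parameter snapshots (the
#' tail of the sampling trajectory) rather than the single final sample,
#' which for a stochastic sampler is an arbitrary draw.  Falls back to
#' the final state when no snapshots were stored.
#'
#' @param fit A `wta_fit` or `deep_fit`.
#' @param samples Held-out dataset tibble.
#' @param n_states Number of tail snapshots to average over.
#' @param seed Integer evaluation seed.
#' @return Accuracy in `[0, 1]`.
#' @export
posterior_test_accuracy <- function(fit, samples, n_states = 3, seed = 1L) {
  deep <- inherits(fit, "deep_fit")
  snaps <- utils::tail(fit$snapshots, n_states)
  if (!length(snaps)) {
    return(if (deep) evaluate_deep(samples, fit, seed = seed)
           else evaluate_accuracy(samples, fit, seed = seed))
  }
  accs <- vapply(snaps, function(s) {
    if (deep) {
      f <- fit
      f$layer1 <- s$layer1
      f$layer2 <- s$layer2
      evaluate_deep(samples, f, seed = seed)
    } else {
      evaluate_accuracy(samples, s, fit$bank, K = fit$K,
                        R_total = fit$R_total, T_ms = fit$T_ms,
                        dt_ms = fit$dt_ms, kernel = fit$kernel,
                        seed = seed)
    }
  }, numeric(1))
  mean(accs)
}

#' @export
print.noise_comparison <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf(paste0("<noise_comparison: %d-layer, %d runs; mean test ",
                     "accuracy %.1f%% with noise vs %.1f%% without ",
                     "(gain %.1f points)>\n"),
              x$layers, x$profile$n_runs, 100 * g$mean_test_with,
              100 * g$mean_test_without, 100 * g$test_gain))
  invisible(x)
}

#' Export a concatenated output-spike raster for trained weights
#'
#' Presents `n_samples` held-out samples back to back (one 200-ms window
#' each, giving a 4-s epoch for the default 20) and records every output
#' spike with its global time.  A preference-pattern score — the fraction
#' of output spikes emitted by the neuron matching the sample's label — is
#' attached; chance level is `1/K`, a perfectly specialised network scores
#' close to 1.
#'
#' @param fit A `wta_fit` or `deep_fit`.
#' @param samples Dataset tibble; the first `n_samples` rows are used.
#' @param n_samples Number of presentations (default 20).
#' @param path Optional file path; the raster is written in the
#'   two-column spike text format.
#' @param seed Integer seed.
#' @return Tibble of output spikes (`neuron`, `time_ms`, `sample`,
#'   `label`) with attribute `preference_score`.
#' @export
export_raster <- function(fit, samples, n_samples = 20, path = NULL,
                          seed = 1L) {
  samples <- utils::head(samples, n_samples)
  cm <- conv_matrix(round(fit$T_ms / fit$dt_ms), fit$kernel)
  feats <- feature_matrix(samples)
  set.seed(as.integer(seed))
  deep <- inherits(fit, "deep_fit")
  out_rows <- list()
  n_match <- 0L; n_tot <- 0L
  for (i in seq_len(nrow(samples))) {
    rates <- firing_rates(feats[i, ], fit$bank)
    x <- cm %*% poisson_spike_matrix(rates, fit$T_ms, fit$dt_ms)
    if (deep) {
      hf <- hidden_forward(x, fit$layer1, cm = cm,
                           R_hidden = fit$R_hidden, dt_ms = fit$dt_ms,
                           group_size = fit$group_size %||% 5L)
      x <- hf$y
    }
    w_out <- if (deep) fit$layer2$w else fit$state$w
    res <- sample_output_spikes(wta_rates(x %*% t(w_out), fit$R_total),
                                fit$dt_ms)
    sp <- res$spikes
    lab <- samples$label[i]
    n_match <- n_match + sum(sp$neuron - 1L == lab)
    n_tot <- n_tot + nrow(sp)
    out_rows[[i]] <- tibble::tibble(neuron = sp$neuron,
                                    time_ms = sp$time_ms +
                                      (i - 1) * fit$T_ms,
                                    sample = i, label = lab)
  }
  raster <- dplyr::bind_rows(out_rows)
  attr(raster, "T_ms") <- nrow(samples) * fit$T_ms
  attr(raster, "dt_ms") <- fit$dt_ms
  attr(raster, "n_neurons") <- fit$K
  attr(raster, "preference_score") <- if (n_tot) n_match / n_tot else NA_real_
  if (!is.null(path)) write_spikes(raster, path)
  raster
}

#' Strict-saddle counting pipeline over a paired comparison
#'
#' For each seed pair, takes the stored tail snapshots of both training
#' arms, presents the same held-out inputs (shared Poisson encodings) to
#' every snapshot, and counts the (snapshot, input) pairs whose Hessian
#' trace certificate holds.  `S1` is the total over noise-trained
#' snapshots, `S2` over noiseless-trained snapshots; the reduction rate is
#' `(S2 - S1) / S2` (undefined when `S2 = 0`).
#'
#' @param comparison A [run_comparison()] result with snapshots.
#' @param n_inputs Held-out inputs per run (defaults to the profile
#'   setting).
#' @param seed Integer seed for the shared encodings.
#' @return Object of class `saddle_report`: list with `summary` (one-row
#'   tibble: `S1`, `S2`, `reduction_rate_pct`), `per_run` tibble, and the
#'   per-pair `detail`.
#' @export
run_saddle_pipeline <- function(comparison, n_inputs = NULL, seed = 1L) {
  stopifnot(inherits(comparison, "noise_comparison"))
  n_inputs <- n_inputs %||% comparison$profile$n_saddle_inputs
  cfg <- comparison$config
  per_run <- list()
  details <- list()
  for (r in seq_along(comparison$runs)) {
    run <- comparison$runs[[r]]
    if (!length(run$with_noise$snapshots))
      stop("run ", r, " has no stored snapshots; re-run run_comparison()",
           " with snapshots = TRUE", call. = FALSE)
    inputs <- utils::head(run$test, n_inputs)
    traces <- precompute_traces(inputs, run$bank, seed = seed + r)
    counts <- numeric(2)
    names(counts) <- c("with_noise", "without_noise")
    for (cond in names(counts)) {
      fit <- run[[cond]]
      snaps <- lapply(fit$snapshots, function(s)
        if (inherits(s, "synapse_state")) s else s$layer2)
      stats_per_snap <- lapply(snaps, function(s) {
        st <- if (inherits(fit, "deep_fit")) {
          # deep snapshots: certificate applies to the output layer driven
          # by the snapshot's own hidden layer
          snapshot_deep_stats(fit, s, inputs, traces, seed + r)
        } else {
          snapshot_input_stats(s, inputs, run$bank, K = fit$K,
                               R_total = fit$R_total, T_ms = fit$T_ms,
                               dt_ms = fit$dt_ms, traces = traces,
                               seed = seed + r)
        }
        st
      })
      cc <- count_certified(unname(snaps), unname(stats_per_snap),
                            sigma = cfg$sigma, mu = cfg$mu,
                            alpha = cfg$alpha)
      counts[cond] <- as.integer(cc)
      d <- attr(cc, "detail")
      d$run <- r
      d$condition <- cond
      details[[length(details) + 1L]] <- d
    }
    per_run[[r]] <- tibble::tibble(run = r, S1 = counts["with_noise"],
                                   S2 = counts["without_noise"])
  }
  per_run <- dplyr::bind_rows(per_run)
  S1 <- sum(per_run$S1); S2 <- sum(per_run$S2)
  rate <- if (S2 > 0) reduction_rate(S1, S2) else NA_real_
  structure(list(summary = tibble::tibble(S1 = S1, S2 = S2,
                                          reduction_rate_pct = 100 * rate),
                 per_run = per_run, detail = dplyr::bind_rows(details)),
            class = "saddle_report")
}

# forward stats for a deep snapshot: hidden pass under the snapshot's own
# first layer, certificate stats on the output layer
snapshot_deep_stats <- function(fit, state2, inputs, traces, seed) {
  snap_pairs <- fit$snapshots
  # locate the matching layer1 for this layer2 snapshot
  l1 <- NULL
  for (s in snap_pairs)
    if (!inherits(s, "synapse_state") && identical(s$layer2, state2))
      l1 <- s$layer1
  if (is.null(l1)) l1 <- fit$layer1
  ids <- inputs$sample_id %||% seq_len(nrow(inputs))
  out <- vector("list", nrow(inputs))
  for (i in seq_len(nrow(inputs))) {
    set.seed(as.integer((as.numeric(seed) * 131 + ids[i] * 7919) %%
                          2147483647))
    hf <- hidden_forward(traces[[i]], l1, cm = NULL,
                         R_hidden = fit$R_hidden, dt_ms = fit$dt_ms,
                         kernel = fit$kernel,
                         group_size = fit$group_size %||% 5L)
    res <- sample_output_spikes(wta_rates(hf$y %*% t(state2$w),
                                          fit$R_total), fit$dt_ms)
    out[[i]] <- list(s_bar = res$s_bar, s_total = res$counts,
                     h = one_hot(inputs$label[i], fit$K),
                     label_hat = res$label)
  }
  out
}

#' @export
print.saddle_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<saddle_report: S1=%d (with noise), S2=%d (without), reduction rate %s>\n",
              s$S1, s$S2,
              if (is.na(s$reduction_rate_pct)) "undefined"
              else sprintf("%.2f%%", s$reduction_rate_pct)))
  invisible(x)
}
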