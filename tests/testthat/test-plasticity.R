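test_that("the parameter-to-weight mapping is exponential and monotone", {
  th <- matrix(c(3, 3 + log(2), 1, 5), 2, 2)
  w <- weights_from_params(th, 3)
  expect_equal(w[1, 1], 1)
  expect_equal(w[2, 1], 2)
  expect_true(all(w > 0))
  expect_true(all(weights_from_params(th + 0.1, 3) > w))
})

test_that("prior drift pulls theta towards the prior mean", {
  expect_equal(prior_drift(matrix(0.5, 2, 2), 0.5, 1),
               matrix(0, 2, 2))
  expect_equal(prior_drift(matrix(1, 1, 1), 0, 1)[1, 1], -1)
  expect_equal(prior_drift(matrix(-2, 1, 1), 0, 2)[1, 1], 0.5)
  expect_error(prior_drift(matrix(0, 1, 1), 0, 0), "positive")
})

test_that("STDP drift has the documented fixed points and sign structure", {
  alpha <- exp(-6)
  w <- matrix(c(0.5, 1, 2, 0.2, 0.9, 1.5), 2, 3)
  # fixed point 1: xbar equals the weight-dependent threshold
  wu <- matrix(0.5, 2, 3)
  d1 <- stdp_drift(rep(alpha * exp(0.5), 3), c(1, 0), c(0, 1), wu, alpha)
  expect_equal(d1, matrix(0, 2, 3), ignore_attr = TRUE)
  # fixed point 2: perfectly correct output
  d2 <- stdp_drift(c(1, 1, 1), c(1, 0), c(1, 0), w, alpha)
  expect_equal(d2, matrix(0, 2, 3), ignore_attr = TRUE)

  # wrong neuron fires with strong input: depression on the firing row,
  # potentiation on the label row
  xbar <- rep(1, 3)                 # well above alpha * e^w here
  d3 <- stdp_drift(xbar, s_bar = c(1, 0), h = c(0, 1), w, alpha)
  expect_true(all(d3[1, ] < 0))
  expect_true(all(d3[2, ] > 0))

  expect_error(stdp_drift(c(1, 1), c(1, 0), c(0, 1), w, alpha), "mismatch")
})

test_that("noise increment has the weight-dependent scale", {
  cfg <- plasticity_config(noise_on = FALSE)
  expect_equal(noise_increment(matrix(1, 3, 3), cfg), matrix(0, 3, 3),
               ignore_attr = TRUE)

  # variance reading (default): sd = sqrt(N alpha e^w)
  cfg <- plasticity_config()
  w <- matrix(1, 200, 500)
  draws <- noise_increment(w, cfg, seed = 42)
  expect_equal(stats::sd(draws), sqrt(1000 * exp(-6) * exp(1)),
               tolerance = 0.02)

  # std reading: sd = N alpha e^w; at w = 1 this is 1000 e^-5 ~ 6.738
  cfg_std <- plasticity_config(noise_param_is_std = TRUE)
  draws_std <- noise_increment(w, cfg_std, seed = 43)
  expect_equal(stats::sd(draws_std), 1000 * exp(-5), tolerance = 0.02)
  expect_equal(1000 * exp(-5), 6.738, tolerance = 1e-3)
  expect_lt(abs(mean(draws_std)), 3 * 6.738 / sqrt(length(w)))

  # monotone in w
  w2 <- matrix(2, 100, 500)
  expect_gt(stats::sd(noise_increment(w2, cfg, seed = 2)),
            stats::sd(noise_increment(w / 2, cfg, seed = 2)))
})

test_that("sampling_step is deterministic, clipped, and inert at b = 0", {
  cfg0 <- plasticity_config(b = 0)
  st <- init_synapses(3, 4, cfg0, seed = 1)
  stats <- list(xbar = runif(4), s_bar = c(1, 0, 0), h = c(0, 1, 0))
  expect_equal(sampling_step(st, stats, cfg0)$theta, st$theta)

  # zero drift and noise off -> unchanged
  cfg <- plasticity_config(noise_on = FALSE)
  st_mu <- synapse_state(matrix(cfg$mu, 2, 2), cfg$theta0)
  expect_equal(sampling_step(st_mu, NULL, cfg)$theta, st_mu$theta)

  # bitwise-identical under a fixed RNG state
  cfg_n <- plasticity_config()
  r1 <- { set.seed(9); sampling_step(st, stats, cfg_n) }
  r2 <- { set.seed(9); sampling_step(st, stats, cfg_n) }
  expect_identical(r1$theta, r2$theta)

  # clipping keeps theta in range under extreme drift
  cfg_big <- plasticity_config(b = 100, noise_on = FALSE)
  big <- sampling_step(st, stats, cfg_big)
  expect_true(all(big$theta >= -10 & big$theta <= 8))
})

test_that("with likelihood and noise off, theta follows the prior ODE", {
  # theta(t) = mu + (theta_init - mu) exp(-b t / sigma^2), closed form of
  # the pure prior pull; Euler integration should track it closely
  cfg <- plasticity_config(b = 1e-3, noise_on = FALSE, mu = 0.5, sigma = 1,
                           dt_update = 1)
  st <- synapse_state(matrix(c(-2, 0, 3, 5), 2, 2), cfg$theta0)
  th0 <- st$theta
  n_steps <- 2000
  for (i in seq_len(n_steps)) st <- sampling_step(st, NULL, cfg)
  closed <- 0.5 + (th0 - 0.5) * exp(-cfg$b * n_steps / cfg$sigma^2)
  expect_equal(st$theta, closed, tolerance = 1e-3)
  # monotone approach
  expect_true(all(abs(st$theta - 0.5) < abs(th0 - 0.5)))
})

test_that("training learns a linearly separable two-class toy task", {
  # two disjoint input channels; class 0 drives neuron 1, class 1 drives
  # neuron 2 (pixel-mode encoding so tuning is exact).  The drive is
  # strong (r_max = 200 Hz) so the softmax saturates at moderate weights,
  # and the step is small so the plateau is reached without overshoot.
  bank <- tuning_bank(2, 2, mode = "pixel", r_max = 200)
  n <- 1000
  labels <- rep(0:1, length.out = n)
  d <- tibble::tibble(sample_id = 1:n,
                      f1 = as.numeric(labels == 0),
                      f2 = as.numeric(labels == 1),
                      label = labels)
  cfg <- plasticity_config(noise_on = FALSE, dt_update = 1)
  fit <- train_wta(d, bank, cfg, K = 2, seed = 3)
  expect_gte(max(utils::tail(fit$curve$accuracy, 3)), 0.8)
  acc <- evaluate_accuracy(utils::head(d, 300), fit, seed = 5)
  expect_gte(acc, 0.9)
})

test_that("evaluation is chance-level for uniform weights and order invariant", {
  env <- tiny_env(n_classes = 5, n_neurons = 40, seed = 2)
  d <- generate_dataset(env$params, 400, seed = 3)
  st <- synapse_state(matrix(0, 5, 40), 3)   # uniform weights
  acc <- evaluate_accuracy(d, st, env$bank, K = 5, seed = 7)
  expect_lt(abs(acc - 0.2), 3 * sqrt(0.2 * 0.8 / 400) + 0.02)

  # shuffling rows leaves the accuracy unchanged (per-sample seeding)
  d_shuf <- d[sample(nrow(d)), ]
  expect_equal(evaluate_accuracy(d_shuf, st, env$bank, K = 5, seed = 7), acc)

  # oracle weights classify perfectly: each class gets one dedicated
  # strongly-weighted input neuron via pixel encoding
  bank <- tuning_bank(3, 3, mode = "pixel")
  d3 <- tibble::tibble(sample_id = 1:30,
                       f1 = rep(c(1, 0, 0), 10),
                       f2 = rep(c(0, 1, 0), 10),
                       f3 = rep(c(0, 0, 1), 10),
                       label = rep(0:2, 10))
  th <- matrix(0, 3, 3); diag(th) <- 5
  st3 <- synapse_state(th, 0)
  expect_equal(evaluate_accuracy(d3, st3, bank, K = 3, seed = 1), 1)

  expect_error(evaluate_accuracy(d3[0, ], st3, bank), "empty")
})

test_that("training records snapshots and one update per sample", {
  env <- tiny_env(n_classes = 3, n_neurons = 20, seed = 4)
  d <- generate_dataset(env$params, 5, seed = 5)
  cfg <- plasticity_config(noise_on = FALSE)
  fit <- train_wta(d, env$bank, cfg, K = 3, snapshot_at = c(2, 5), seed = 6)
  expect_named(fit$snapshots, c("2", "5"))
  expect_false(identical(fit$snapshots[["2"]]$theta,
                         fit$snapshots[["5"]]$theta))

  # single-sample dataset: exactly one update from the initial state
  d1 <- d[1, ]
  f1 <- train_wta(d1, env$bank, cfg, K = 3, snapshot_at = 1, seed = 6)
  expect_equal(f1$snapshots[["1"]]$theta, f1$state$theta)
})

test_that("the noise-off arm is bitwise reproducible", {
  env <- tiny_env(n_classes = 3, n_neurons = 25, seed = 8)
  d <- generate_dataset(env$params, 40, seed = 9)
  cfg <- plasticity_config(noise_on = FALSE)
  f1 <- train_wta(d, env$bank, cfg, K = 3, seed = 11)
  f2 <- train_wta(d, env$bank, cfg, K = 3, seed = 11)
  expect_identical(f1$state$theta, f2$state$theta)
  expect_identical(f1$curve, f2$curve)
})

test_that("per-bin STDP mode zeroes drift for a perfect output stream", {
  # spike stream exactly matching the teaching rate on the label neuron
  cfg <- plasticity_config(stdp_mode = "per_bin", noise_on = FALSE)
  w <- matrix(0.5, 2, 3)
  x <- matrix(0.4, 10, 3)
  s_mat <- matrix(0, 10, 2)
  # label neuron 1 fires at exactly rho_tgt * dt per bin (expected value)
  rho_tgt <- 100
  s_mat[, 1] <- rho_tgt * 1 / 1000
  d <- synsamp:::stdp_drift_bins(x, s_mat, h = c(1, 0), w, exp(-6),
                                 rho_tgt = rho_tgt, dt_ms = 1)
  expect_equal(d, matrix(0, 2, 3), ignore_attr = TRUE)
})
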