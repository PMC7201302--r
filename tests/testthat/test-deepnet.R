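test_that("hidden forward conserves per-group budgets and composes shapes", {
  cfg <- plasticity_config()
  st1 <- init_synapses(10, 6, cfg, seed = 1)
  x <- matrix(runif(300), 50, 6)
  hf <- hidden_forward(x, st1, R_hidden = 200, dt_ms = 1, group_size = 5,
                       keep_spikes = TRUE)
  expect_equal(dim(hf$y), c(50, 10))
  expect_length(hf$ybar, 10)
  expect_true(all(hf$y >= 0))

  # zero input -> uniform within-group competition, traces still bounded
  hf0 <- hidden_forward(matrix(0, 50, 6), st1)
  expect_true(all(hf0$ybar >= 0))

  # at most one spike per group per bin
  sm <- synsamp:::spikes_to_matrix(hf$spikes, n_neurons = 10, T_ms = 50)
  expect_lte(max(rowSums(sm[, 1:5])), 1)
  expect_lte(max(rowSums(sm[, 6:10])), 1)

  expect_error(hidden_forward(matrix(0, 5, 4), st1), "expects")
})

test_that("output_layer_update matches sampling_step and returns the increment", {
  cfg <- plasticity_config(noise_on = FALSE)
  st2 <- init_synapses(3, 8, cfg, seed = 2)
  stats <- list(xbar = runif(8), s_bar = c(0.2, 0.5, 0.3), h = c(0, 1, 0))
  upd <- output_layer_update(st2, stats, cfg)
  direct <- sampling_step(st2, stats, cfg)
  expect_equal(upd$state$theta, direct$theta)
  expect_equal(upd$dtheta, direct$theta - st2$theta)

  # perfect output with zero hidden activity: increment is prior only
  stats0 <- list(xbar = rep(0, 8), s_bar = c(0, 1, 0), h = c(0, 1, 0))
  upd0 <- output_layer_update(st2, stats0, cfg)
  expect_equal(upd0$dtheta,
               cfg$b * cfg$dt_update *
                 prior_drift(st2$theta, cfg$mu, cfg$sigma),
               tolerance = 1e-12)

  # fixed seed reproducibility with noise on
  cfg_n <- plasticity_config(noise_on = TRUE)
  u1 <- { set.seed(5); output_layer_update(st2, stats, cfg_n) }
  u2 <- { set.seed(5); output_layer_update(st2, stats, cfg_n) }
  expect_identical(u1$dtheta, u2$dtheta)
})

test_that("hidden_layer_update implements the back-propagation chain rule", {
  st1 <- state_of(matrix(0, 2, 2), theta0 = 0)
  xbar <- c(0.3, 0.7)
  dL <- matrix(c(0.01, -0.02, 0.03, 0.04), 2, 2)  # K=2 x J=2
  alpha <- exp(-6)

  # zero output increment -> zero hidden update
  z <- hidden_layer_update(st1, xbar, matrix(0, 2, 2), 0, 1, alpha, alpha)
  expect_equal(z$dtheta, matrix(0, 2, 2), ignore_attr = TRUE)

  # hand-computed 2x2x2 case: dtheta_ji = (beta/alpha) xbar_i (dL[k,j]+dL[m,j])
  beta <- alpha
  got <- hidden_layer_update(st1, xbar, dL, k = 0, m = 1, beta, alpha)
  v <- dL[1, ] + dL[2, ]
  expect_equal(got$dtheta, outer(v, xbar), tolerance = 1e-12)

  # doubling beta doubles the update
  got2 <- hidden_layer_update(st1, xbar, dL, 0, 1, 2 * beta, alpha)
  expect_equal(got2$dtheta, 2 * got$dtheta)

  expect_error(hidden_layer_update(st1, xbar, dL, -1, 0, beta, alpha),
               "invalid")
  expect_error(hidden_layer_update(st1, xbar, dL, 0, 5, beta, alpha),
               "invalid")
})

test_that("beta = 0 freezes the first layer (structural reduction)", {
  env <- tiny_env(n_classes = 3, n_neurons = 20, seed = 3)
  d <- generate_dataset(env$params, 15, seed = 4)
  cfg <- plasticity_config(noise_on = FALSE)
  fit <- train_deep(d, env$bank, cfg, J = 6, K = 3, beta = 0,
                    group_size = 3, seed = 5)
  set.seed(5)
  init1 <- init_synapses(6, 20, cfg)
  expect_identical(fit$layer1$theta, init1$theta)

  # beta > 0 moves it
  fitb <- train_deep(d, env$bank, cfg, J = 6, K = 3, beta = cfg$alpha,
                     group_size = 3, seed = 5)
  expect_false(identical(fitb$layer1$theta, init1$theta))
})

test_that("deep training updates each layer once per sample and evaluates", {
  env <- tiny_env(n_classes = 3, n_neurons = 20, seed = 6)
  d <- generate_dataset(env$params, 4, seed = 7)
  cfg <- plasticity_config(noise_on = FALSE)
  fit <- train_deep(d[1, ], env$bank, cfg, J = 6, K = 3,
                    beta = cfg$alpha, group_size = 3,
                    snapshot_at = 1, seed = 8)
  snap <- fit$snapshots[["1"]]
  expect_equal(snap$layer2$theta, fit$layer2$theta)
  expect_equal(snap$layer1$theta, fit$layer1$theta)

  acc <- evaluate_deep(d, fit, seed = 9)
  expect_gte(acc, 0)
  expect_lte(acc, 1)

  # weight positivity holds at every layer after training
  fit2 <- train_deep(d, env$bank, plasticity_config(), J = 6, K = 3,
                     beta = cfg$alpha, group_size = 3, seed = 10)
  expect_true(all(fit2$layer1$w > 0))
  expect_true(all(fit2$layer2$w > 0))
})

test_that("a diagonal-dominant first layer preserves the input argmax", {
  # 3 inputs -> 3 hidden neurons, one group; strong diagonal weights make
  # hidden neuron j follow input j
  th <- matrix(-3, 3, 3); diag(th) <- 3
  st1 <- synapse_state(th, 0)
  x <- matrix(0, 100, 3); x[, 2] <- 1    # input 2 active
  wins <- vapply(1:60, function(s) {
    set.seed(s)
    hf <- hidden_forward(x, st1, R_hidden = 300, group_size = 3)
    which.max(hf$counts)
  }, numeric(1))
  expect_gt(mean(wins == 2), 0.9)
})
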