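test_that("firing rates follow the Gaussian tuning curve with background", {
  bank <- tuning_bank(50, 3, seed = 1)
  # neuron 1 probed exactly at its preferred value on its own coordinate
  v <- rep(10, 3)  # far from every centre (centres within [-0.5, 1.5])
  v[bank$dim_index[1]] <- bank$center[1]
  r <- firing_rates(v, bank)
  expect_equal(r[1], bank$r_max + 5)
  # >= 5 sigma away on a different coordinate -> background only, within 1%
  far <- which(bank$dim_index != bank$dim_index[1])
  expect_lt(max(abs(r[far] - 5)), 0.05 * 5)
  expect_true(all(r >= bank$r_bg))

  # monotone decrease in |v - c|
  b1 <- tuning_bank(1, 1, seed = 2)
  ds <- seq(0, 1, by = 0.1)
  rates <- vapply(ds, function(d) firing_rates(b1$center[1] + d, b1),
                  numeric(1))
  expect_true(all(diff(rates) <= 0))

  expect_error(firing_rates(c(0.5), bank), "incompatible")
})

test_that("pixel mode reads one neuron per feature", {
  bank <- tuning_bank(4, 4, mode = "pixel")
  r <- firing_rates(c(0, 0.5, 1, 0.25), bank)
  expect_equal(r, 80 * c(0, 0.5, 1, 0.25) + 5)
  expect_error(firing_rates(c(1, 2), bank), "n_neurons")
})

test_that("Poisson spiking matches its rate and is seed-deterministic", {
  expect_equal(nrow(poisson_spikes(0, T_ms = 200, seed = 1)), 0)
  s1 <- poisson_spikes(c(20, 50), seed = 3)
  s2 <- poisson_spikes(c(20, 50), seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1$time_ms >= 0 & s1$time_ms < 200))

  # Monte-Carlo oracle: mean count of a 50 Hz train over 200 ms is 10
  counts <- vapply(1:2000, function(s)
    nrow(poisson_spikes(50, T_ms = 200, seed = s)), numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10), 3 * se)

  expect_error(poisson_spikes(-1), "negative")
  expect_error(poisson_spikes(10, T_ms = 205, dt_ms = 2), "multiple")
})

test_that("EPSP traces are causal, linear, and match brute-force convolution", {
  k <- epsp_kernel()
  expect_equal(max(k), 1)                  # peak normalisation
  expect_equal(as.numeric(k)[1], 0)        # zero at lag 0
  expect_true(all(k >= 0))

  ka <- epsp_kernel(normalize = "area")
  expect_equal(sum(ka) * attr(ka, "dt_ms"), 1)

  # empty train -> zero trace
  empty <- poisson_spikes(0, T_ms = 100)
  expect_true(all(epsp_trace(empty, k) == 0))

  # single spike -> shifted kernel with peak 1
  m <- matrix(0, 100, 1)
  m[31, 1] <- 1
  tr <- epsp_trace(m, k)
  expect_true(all(tr[1:30] == 0))
  expect_equal(max(tr), 1)
  expect_equal(tr[31:(30 + length(k)), 1], as.numeric(k))
  expect_true(all(tr[(31 + length(k)):100, 1] == 0))

  # linearity against a brute-force convolution oracle
  set.seed(5)
  sp <- matrix(rbinom(200 * 3, 1, 0.05), 200, 3)
  sp2 <- matrix(rbinom(200 * 3, 1, 0.05), 200, 3)
  brute <- function(s) {
    out <- matrix(0, nrow(s), ncol(s))
    kv <- as.numeric(k)
    for (i in seq_len(ncol(s))) for (t in which(s[, i] > 0))
      for (l in seq_along(kv)) {
        tt <- t + l - 1
        if (tt <= nrow(s)) out[tt, i] <- out[tt, i] + kv[l]
      }
    out
  }
  expect_equal(epsp_trace(sp, k), brute(sp), tolerance = 1e-12)
  expect_equal(epsp_trace(sp + sp2, k),
               epsp_trace(sp, k) + epsp_trace(sp2, k), tolerance = 1e-12)

  # trace bounded by spikes-in-window times peak
  expect_lte(max(epsp_trace(sp, k)), max(colSums(sp)))
})

test_that("mean_trace equals the brute-force time average", {
  expect_error(mean_trace(matrix(numeric(0), 0, 2)), "empty")
  expect_equal(mean_trace(matrix(0, 10, 2)), c(0, 0))
  expect_equal(mean_trace(matrix(3.5, 10, 2)), c(3.5, 3.5))
  set.seed(1)
  m <- matrix(runif(50), 10, 5)
  expect_equal(mean_trace(m), apply(m, 2, function(col) sum(col) / 10))
})

test_that("empirical spike rates agree with the requested tuning rates", {
  bank <- tuning_bank(40, 3, seed = 2)
  v <- c(0.4, 0.6, 0.5)
  r <- firing_rates(v, bank)
  counts <- Reduce(`+`, lapply(1:200, function(s)
    colSums(poisson_spike_matrix <- synsamp:::poisson_spike_matrix(
      r, 200, 1, seed = s))))
  emp_rate <- counts / 200 / 0.2
  se <- sqrt(r / (200 * 0.2))
  expect_true(all(abs(emp_rate - r) < 4 * se + 0.5))
})

test_that("rate spread over a synthetic dataset covers the coding range", {
  env <- tiny_env(n_classes = 10, n_neurons = 200, seed = 3)
  d <- generate_dataset(env$params, 50, seed = 4)
  rates <- unlist(lapply(seq_len(nrow(d)), function(i)
    firing_rates(as.numeric(d[i, c("f1", "f2", "f3")]), env$bank)))
  expect_gte(max(rates), 0.8 * (env$bank$r_max + env$bank$r_bg))
  expect_lte(min(rates), env$bank$r_bg + 1)
})

test_that("spike files round-trip", {
  s <- poisson_spikes(c(30, 60, 10), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spikes(s, path)
  s2 <- read_spikes(path)
  expect_equal(s2$neuron, s$neuron)
  expect_equal(s2$time_ms, s$time_ms)
  expect_equal(attr(s2, "T_ms"), attr(s, "T_ms"))
  expect_equal(attr(s2, "n_neurons"), attr(s, "n_neurons"))
})
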