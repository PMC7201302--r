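# Small shared fixtures, generated in code.

tiny_env <- function(n_classes = 3, n_neurons = 30, seed = 7) {
  params <- sample_cluster_params(n_classes, seed = seed)
  bank <- tuning_bank(n_neurons, 3, seed = seed + 1)
  list(params = params, bank = bank)
}

# a synapse state with prescribed theta values
state_of <- function(theta, theta0 = 3) synapse_state(theta, theta0)

# deterministic one-hot stats for saddle / plasticity tests
stats_of <- function(s_bar, label, K = length(s_bar)) {
  list(s_bar = s_bar, h = one_hot_vec(label, K))
}

one_hot_vec <- function(label, K) {
  h <- numeric(K)
  h[label + 1] <- 1
  h
}
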