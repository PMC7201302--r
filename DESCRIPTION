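Package: synsamp
Title: Noisy Synaptic Sampling in Spiking Winner-Take-All Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates supervised learning in spiking winner-take-all
    circuits under a synaptic-sampling plasticity rule whose stochastic
    term has a weight-dependent scale (standard deviation proportional
    to N*alpha*exp(w)).  Provides a synthetic Gaussian-cluster sensory
    environment, Gaussian tuning-curve Poisson encoders, two- and
    three-layer network trainers with and without the noise term,
    strict-saddle certification diagnostics based on the trace of the
    Hessian of the learning objective, and a reproducible paired-run
    experiment harness.  All user-facing functions take and return
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
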