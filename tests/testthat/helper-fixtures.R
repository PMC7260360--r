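# Shared fixtures: a fast, coarse model parameter set for tests that only
# exercise mechanics (full-resolution defaults are used where the science
# is asserted), and small simulation helpers.

coarse_params <- function(...) {
  norm_model_params(grid_step = 0.2, ...)
}

# deterministic trial set from a known Weibull observer on a fixed design
weibull_trials <- function(alpha, beta, n_per_level = 20,
                           durations = exp(seq(log(10), log(300),
                                               length.out = 12)),
                           gamma = 0.5, lambda = 0.04) {
  d <- rep(durations, each = n_per_level)
  p <- weibull_p(d, alpha, beta, gamma, lambda)
  data.frame(duration_ms = d, correct = runif(length(d)) < p)
}

# minimal observer covering the six task conditions
six_condition_observer <- function(base_ms = 80) {
  grid <- expand.grid(size_deg = c(0.84, 1.7, 10),
                      contrast = c(0.03, 0.98))
  grid$threshold_ms <- base_ms * seq(0.8, 1.8, length.out = 6)
  observer_spec(grid)
}
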