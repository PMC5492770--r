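# Small shared builders: sessions are generated in code, never stored.

tiny_grip_cfg <- function(seed = 1, ...) {
  sim_config("grip", seed = seed, ...)
}

tiny_grip_session <- function(seed = 1, n_episodes = 4) {
  simulate_session(tiny_grip_cfg(seed), n_episodes)
}

random_training_set <- function(n = 20, d = 3, L = 2, seed = 42) {
  set.seed(seed)
  list(x = matrix(rnorm(n * d), n, d),
       y = matrix(rnorm(n * L), n, L, dimnames = list(NULL, paste0("y", 1:L))))
}

# Direct per-layer GRNN oracle: explicit loop over the pattern, sum and
# output layers, independent of the vectorized implementation.
grnn_oracle <- function(model, probe) {
  x_std <- (probe - model$center) / model$scale
  p <- numeric(model$n)
  for (i in seq_len(model$n)) {
    diff <- x_std - model$x[i, ]
    p[i] <- exp(-sum(diff * diff) / (2 * model$sigma^2))
  }
  s_d <- sum(p)
  vapply(seq_len(model$L), function(j) sum(model$y[, j] * p) / s_d, numeric(1))
}
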