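# Shared fixtures: all models are generated in code at test time.

# random model with deterministic (permutation) transitions and, optionally,
# a one-hot initial prior -- the regime where the mean-field family contains
# the exact posterior (a single state chain)
det_chain_model <- function(seed, n_states = 3, det_D = TRUE) {
  m <- random_model(n_states, 2, 2, 2, 2, seed = seed)
  set.seed(seed)
  for (u in seq_along(m$B)) m$B[[u]] <- diag(n_states)[, sample(n_states)]
  if (det_D) m$D <- as.numeric(diag(n_states)[, sample(n_states, 1)])
  m
}

# beliefs with arbitrary (normalised) random entries, shared across schemes
rand_beliefs <- function(model, seed = 1) {
  set.seed(seed)
  b <- aimdp:::init_beliefs(model)
  for (p in seq_len(model$n_policies))
    for (tau in seq_len(model$T))
      b$s[, tau, p] <- softmax(rnorm(model$n_states))
  b$pi <- softmax(rnorm(model$n_policies))
  aimdp:::refresh_outcomes(model, b)
}

# independent forward-algorithm evidence, P(o*_1..t) summed over policies --
# a cross-check for the enumeration oracle that never enumerates sequences
forward_evidence <- function(model, obs, t = obs$t) {
  total <- 0
  E <- model$E / sum(model$E)
  for (p in seq_len(model$n_policies)) {
    alpha <- model$D
    for (tau in seq_len(model$T)) {
      if (tau > 1) alpha <- as.numeric(model$B[[model$U[tau - 1, p]]] %*% alpha)
      if (tau <= t)
        for (m in seq_len(model$n_modalities))
          alpha <- alpha * model$A[[m]][obs$o[m, tau], ]
    }
    total <- total + E[p] * sum(alpha)
  }
  log(total)
}

# a sampled observation record for a model (full trajectory, truncated to t)
sample_obs <- function(model, seed = 1, t = model$T) {
  tr <- run_trial(model, "efe", seed = seed)
  obs_record(model, tr$observations[, seq_len(t), drop = FALSE], t = t)
}

tmaze_arm_mass <- function(bma, tau) sum(bma[c(2, 3, 6, 7), tau])
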