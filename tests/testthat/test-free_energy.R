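test_that("variational free energy reduces to -log-likelihood for a single
           configuration", {
  # one state, one policy, T = 1: F = -ln P(o|s) - ln D = -ln P(o|s)
  A <- matrix(c(0.7, 0.3), 2, 1)
  m <- mdp_model(A = A, B = matrix(1, 1, 1), C = c(0, 0), D = 1,
                 U = matrix(integer(0), 0, 1), horizon = 1)
  b <- aimdp:::init_beliefs(m)
  obs <- obs_record(m, matrix(1L, 1, 1), t = 1)
  f <- vfe(m, b, obs)
  expect_equal(f$F_p[1], -log(0.7), tolerance = 1e-12)
})

test_that("future variational terms are non-negative complexity costs", {
  for (k in 1:10) {
    m <- random_model(3, 2, 2, 3, 3, seed = k)
    b <- rand_beliefs(m, seed = k)
    obs <- sample_obs(m, seed = k, t = 1)
    f <- vfe(m, b, obs)
    expect_true(all(f$F_pt[2:3, ] >= -1e-10),
                info = sprintf("model seed %d", k))
  }
})

test_that("the bound is tight when beliefs hold the exact posterior", {
  # T = 1: exact posteriors are within the mean-field family
  for (k in 1:5) {
    m <- random_model(3, 2, 2, 2, 1, seed = k)
    obs <- sample_obs(m, seed = k, t = 1)
    b <- oracle_beliefs(m, obs)
    expect_lt(abs(jensen_gap(m, obs, b)), 1e-8)
  }
  # deterministic chain (one-hot D, permutation B): posterior is a single
  # sequence, again within the family
  for (k in 1:5) {
    m <- det_chain_model(k)
    obs <- sample_obs(m, seed = k, t = 2)
    b <- oracle_beliefs(m, obs)
    expect_lt(abs(jensen_gap(m, obs, b)), 1e-8)
  }
})

test_that("expected free energy decompositions agree and have the right
           signs", {
  for (k in 1:10) {
    m <- random_model(4, c(2, 3), 2, 3, 3, seed = k)
    b <- rand_beliefs(m, seed = k)
    t <- k %% 3
    g <- efe(m, b, t)
    fut <- (t + 1):m$T
    # risk + ambiguity = -epistemic - extrinsic, per policy and time
    expect_equal(g$G_pt[fut, ], (-g$epistemic - g$extrinsic)[fut, ],
                 tolerance = 1e-10)
    expect_true(all(g$risk >= -1e-10))
    expect_true(all(g$ambiguity >= -1e-10))
    # mutual information bounded by the outcome entropy (per modality sums)
    expect_true(all(g$epistemic >= -1e-10))
    # no contributions at or before the current time
    if (t > 0) expect_true(all(g$G_pt[seq_len(t), ] == 0))
  }
})

test_that("outcome-independent likelihoods carry no epistemic value", {
  A <- matrix(0.5, 2, 3) # identical columns
  m <- random_model(3, 2, 2, 2, 2, seed = 1)
  m$A <- list(A)
  m$C <- m$C[1]
  m$n_modalities <- 1L
  m$n_outcomes <- 2L
  b <- rand_beliefs(m, seed = 3)
  g <- efe(m, b, 0)
  expect_equal(max(abs(g$epistemic)), 0, tolerance = 1e-12)
})

test_that("deterministic likelihood with preference-matching predictions
           zeroes the expected free energy", {
  # identity A, beliefs equal to exp(C): risk = 0 and ambiguity = 0
  n <- 3
  m <- random_model(n, n, 1, 1, 2, seed = 5)
  m$A <- list(diag(n))
  cvec <- aimdp:::lsoftmax(c(0.3, -0.2, 0.1))
  m$C <- list(matrix(cvec, n, m$T))
  b <- aimdp:::init_beliefs(m)
  for (tau in 1:m$T) b$s[, tau, 1] <- exp(cvec)
  b <- aimdp:::refresh_outcomes(m, b)
  g <- efe(m, b, 0)
  expect_equal(max(abs(g$G_pt)), 0, tolerance = 1e-10)
})

test_that("generalised free energy reduces as observations arrive", {
  for (k in 1:6) {
    m <- random_model(3, 2, 2, 3, 3, seed = 20 + k)
    b <- rand_beliefs(m, seed = k)
    # t = 0: GG equals the free energy of the expected future
    obs0 <- obs_record(m, t = 0)
    gg0 <- gfe(m, b, obs0)
    expect_equal(gg0$GG_p, gg0$G_future_p, tolerance = 1e-12)
    # t = T: GG minus F is the same (flat outcome prior) constant for all
    # policies
    obsT <- sample_obs(m, seed = k, t = m$T)
    ggT <- gfe(m, b, obsT)
    fT <- vfe(m, b, obsT)
    diffs <- ggT$GG_p - fT$F_p
    expect_equal(max(diffs) - min(diffs), 0, tolerance = 1e-10)
    expect_equal(diffs[1], m$T * sum(log(m$n_outcomes)), tolerance = 1e-10)
  }
})

test_that("generalised decomposition identities hold with non-negative
           KL-type parts", {
  for (k in 1:10) {
    m <- random_model(4, c(2, 3), 2, 3, 3, seed = 30 + k)
    b <- rand_beliefs(m, seed = k)
    obs <- sample_obs(m, seed = k, t = k %% 3)
    gg <- gfe(m, b, obs)
    fut <- (obs$t + 1):m$T
    expect_equal(gg$G_future_pt[fut, ],
                 (gg$complexity + gg$risk + gg$ambiguity)[fut, ],
                 tolerance = 1e-10)
    expect_equal(gg$G_future_pt[fut, ],
                 (gg$complexity - gg$mutual_information - gg$extrinsic)[fut, ],
                 tolerance = 1e-10)
    expect_true(all(gg$complexity >= -1e-10))
    expect_true(all(gg$risk >= -1e-10))
    expect_true(all(gg$ambiguity >= -1e-10))
    expect_true(all(gg$mutual_information >= -1e-10))
  }
})

test_that("policy posteriors agree between schemes for arbitrary shared
           beliefs", {
  for (k in 1:20) {
    m <- random_model(3, 2, 2, 4, 3, seed = 40 + k)
    b <- rand_beliefs(m, seed = k)
    obs <- sample_obs(m, seed = k, t = k %% 4)
    fv <- vfe(m, b, obs)
    fg <- efe(m, b, obs$t)
    gg <- gfe(m, b, obs)
    p_efe <- softmax(aimdp:::ln(m$E) - fv$F_p - fg$G_p)
    p_gfe <- softmax(aimdp:::ln(m$E) - gg$GG_p)
    expect_equal(p_efe, p_gfe, tolerance = 1e-10)
  }
})

test_that("marginal outcome entropy behaves like a Shannon entropy", {
  expect_equal(marginal_outcome_entropy(c(0, 1, 0)), 0, tolerance = 1e-12)
  expect_equal(marginal_outcome_entropy(rep(0.25, 4)), log(4),
               tolerance = 1e-10)
  v <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(marginal_outcome_entropy(v),
               marginal_outcome_entropy(rev(v)))
  expect_error(marginal_outcome_entropy(c(0.5, 0.6)),
               class = "aimdp_config_error")
})

test_that("breakdowns flatten to a long table", {
  m <- random_model(3, 2, 2, 2, 2, seed = 1)
  b <- rand_beliefs(m)
  g <- efe(m, b, 0)
  df <- as.data.frame(g)
  expect_true(all(c("policy", "tau", "term", "value") %in% names(df)))
  expect_true(all(c("risk", "ambiguity") %in% df$term))
  expect_equal(nrow(df[df$term == "risk", ]), m$T * m$n_policies)
})
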