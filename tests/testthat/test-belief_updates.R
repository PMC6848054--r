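test_that("predictive outcomes are likelihood projections", {
  expect_equal(predictive_outcomes(diag(3), c(0.2, 0.3, 0.5)),
               c(0.2, 0.3, 0.5))
  A <- matrix(c(.2, .8, .6, .4, .5, .5), 2, 3)
  s <- rep(1 / 3, 3)
  expect_equal(predictive_outcomes(A, s), rowMeans(A))
  expect_error(predictive_outcomes(A, c(1, 1, 1)),
               class = "aimdp_config_error")
  # T-maze: certainty about (location 4, context 2) predicts CS-green
  m <- build_tmaze()
  s8 <- aimdp:::one_hot(8, 8)
  expect_equal(predictive_outcomes(m$A[[2]], s8), c(0, 1, 0, 0))
})

test_that("the T = 1 state update is exact Bayes", {
  for (msgs in c("marginal", "vmp")) for (k in 1:5) {
    m <- random_model(4, 3, 1, 1, 1, seed = k)
    o <- sample(3, 1)
    obs <- obs_record(m, matrix(o, 1, 1), t = 1)
    b <- aimdp:::init_beliefs(m)
    s <- update_states_vfe(m, b, obs, 1, 1, messages = msgs)
    bayes <- m$A[[1]][o, ] * m$D
    bayes <- bayes / sum(bayes)
    expect_equal(s, bayes, tolerance = 1e-9)
  }
})

test_that("uniform models stay uniform under every update", {
  n <- 3
  m <- random_model(n, n, 2, 2, 3, seed = 1)
  for (u in seq_along(m$B)) m$B[[u]] <- matrix(1 / n, n, n)
  m$A <- list(matrix(1 / n, n, n))
  m$C <- list(matrix(0, n, m$T))
  m$n_modalities <- 1L
  m$n_outcomes <- n
  m$D <- rep(1 / n, n)
  b <- aimdp:::init_beliefs(m)
  obs <- obs_record(m, matrix(1L, 1, 1), t = 1)
  for (p in 1:m$n_policies) for (tau in 1:m$T) {
    expect_equal(update_states_vfe(m, b, obs, p, tau), rep(1 / n, n))
    expect_equal(update_states_gfe(m, b, obs, p, tau), rep(1 / n, n))
  }
})

test_that("converged beliefs are fixed points of their update equations", {
  for (sc in c("efe", "gfe")) for (msgs in c("marginal", "vmp")) {
    m <- random_model(3, 2, 2, 3, 3, seed = 11)
    obs <- sample_obs(m, seed = 11, t = 2)
    b <- infer(m, obs, sc, messages = msgs, tol = 1e-10, max_iters = 300)
    expect_true(b$converged)
    upd <- if (sc == "efe") update_states_vfe else update_states_gfe
    for (p in 1:m$n_policies) for (tau in 1:m$T) {
      s_new <- upd(m, b, obs, p, tau, messages = msgs)
      expect_lt(max(abs(s_new - b$s[, tau, p])), 1e-6)
    }
  }
})

test_that("past-time generalised updates equal the variational updates", {
  m <- build_tmaze()
  obs <- obs_record(m, matrix(c(1L, 1L), 2, 1), t = 1)
  b <- rand_beliefs(m, seed = 2)
  for (p in c(1, 5, 10))
    expect_identical(update_states_gfe(m, b, obs, p, 1),
                     update_states_vfe(m, b, obs, p, 1))
})

test_that("all-uniform likelihoods reduce the generalised update to
           transition messages", {
  n <- 3
  m <- random_model(n, 2, 2, 2, 3, seed = 3)
  m$A <- list(matrix(0.5, 2, n))
  m$C <- m$C[1]
  m$n_modalities <- 1L
  m$n_outcomes <- 2L
  b <- rand_beliefs(m, seed = 3)
  obs <- obs_record(m, t = 0)
  for (p in 1:2) for (tau in 2:3) {
    gfe_up <- update_states_gfe(m, b, obs, p, tau)
    vfe_up <- update_states_vfe(m, b, obs, p, tau) # no likelihood at tau > t
    expect_equal(gfe_up, vfe_up, tolerance = 1e-12)
  }
})

test_that("policy updates follow softmax arithmetic", {
  expect_equal(update_policies(c(.5, .5), c(1, 1), c(2, 2), "efe"),
               c(.5, .5))
  # (F+G) gap of ln 9 gives a 0.9 / 0.1 split
  pi <- update_policies(c(.5, .5), c(0, 0), c(0, log(9)), "efe")
  expect_equal(pi, c(0.9, 0.1), tolerance = 1e-12)
  pi2 <- update_policies(c(.5, .5), NULL, c(0, log(9)), "gfe")
  expect_equal(pi2, c(0.9, 0.1), tolerance = 1e-12)
  expect_error(update_policies(c(.5, .5), c(1, 1), c(1, 1, 1), "efe"),
               class = "aimdp_structure_error")
})

test_that("Bayesian model averaging mixes policy-conditioned beliefs", {
  m <- random_model(3, 2, 2, 2, 2, seed = 4)
  b <- rand_beliefs(m, seed = 4)
  # single policy: average is that policy's beliefs
  expect_equal(bma_states(c(1, 0), b$s), b$s[, , 1])
  # equal weights: arithmetic mean
  expect_equal(bma_states(c(.5, .5), b$s), (b$s[, , 1] + b$s[, , 2]) / 2)
  out <- bma_states(b$pi, b$s)
  expect_equal(colSums(out), rep(1, m$T))
})

test_that("inference preserves normalisation and converges on small models", {
  for (sc in c("efe", "gfe")) for (k in 1:5) {
    m <- random_model(3, 2, 2, 3, 2, seed = 50 + k)
    obs <- sample_obs(m, seed = k, t = 1)
    b <- infer(m, obs, sc)
    expect_true(b$converged)
    expect_equal(apply(b$s, c(2, 3), sum),
                 matrix(1, m$T, m$n_policies), tolerance = 1e-9)
    expect_equal(sum(b$pi), 1, tolerance = 1e-10)
    for (mm in seq_along(b$o))
      expect_equal(apply(b$o[[mm]], c(2, 3), sum),
                   matrix(1, m$T, m$n_policies), tolerance = 1e-9)
  }
})

test_that("single-policy T = 1 inference equals the exact posterior in one
           sweep", {
  m <- random_model(3, 2, 1, 1, 1, seed = 9)
  obs <- sample_obs(m, seed = 9, t = 1)
  b <- infer(m, obs, "efe")
  ob <- oracle_beliefs(m, obs)
  expect_equal(b$s[, 1, 1], ob$s[, 1, 1], tolerance = 1e-9)
  expect_lte(nrow(b$trace), 2) # one sweep to solve, one to certify
})

test_that("end-to-end scheme posteriors agree when computed from identical
           beliefs", {
  # fix the state beliefs; only the policy update differs between schemes
  m <- random_model(3, 2, 2, 4, 3, seed = 12)
  b <- rand_beliefs(m, seed = 12)
  obs <- sample_obs(m, seed = 12, t = 2)
  fv <- vfe(m, b, obs)
  fg <- efe(m, b, obs$t)
  gg <- gfe(m, b, obs)
  expect_equal(update_policies(m$E, fv$F_p, fg$G_p, "efe"),
               update_policies(m$E, NULL, gg$GG_p, "gfe"),
               tolerance = 1e-10)
})

test_that("variational free energy descends monotonically under exact
           coordinate updates", {
  # the literal mean-field convention minimises each policy's F exactly
  for (k in 1:10) {
    m <- random_model(3, 2, 2, 3, 2, seed = 60 + k)
    obs <- sample_obs(m, seed = k, t = k %% 3)
    be <- infer(m, obs, "efe", messages = "vmp")
    if (nrow(be$trace_F) > 1)
      expect_true(all(diff(be$trace_F) <= 1e-10),
                  info = sprintf("seed %d", 60 + k))
    bg <- infer(m, obs, "gfe", messages = "vmp")
    if (nrow(bg$trace) > 1)
      expect_true(all(diff(bg$trace$total) <= 1e-8),
                  info = sprintf("seed %d (gfe)", 60 + k))
  }
})

test_that("gradient flow shares fixed points with the discrete updates", {
  m <- random_model(3, 2, 2, 2, 2, seed = 13)
  obs <- sample_obs(m, seed = 13, t = 1)
  b <- infer(m, obs, "efe", tol = 1e-12, max_iters = 500)
  # rate 0 is the identity
  s0 <- gradient_flow_step(m, b, obs, 1, 2, rate = 0)
  expect_equal(s0, b$s[, 2, 1], tolerance = 1e-12)
  # at a fixed point a step changes nothing
  s1 <- gradient_flow_step(m, b, obs, 1, 2, rate = 0.3)
  expect_lt(max(abs(s1 - b$s[, 2, 1])), 1e-9)
  # small-rate iteration converges to the same point
  b2 <- aimdp:::init_beliefs(m)
  for (it in 1:2000)
    for (p in 1:m$n_policies) for (tau in 1:m$T)
      b2$s[, tau, p] <- gradient_flow_step(m, b2, obs, p, tau, rate = 0.1)
  expect_lt(max(abs(b2$s - b$s)), 1e-6)
})

test_that("the generalised scheme distorts T-maze futures optimistically", {
  m <- build_tmaze()
  obs <- obs_record(m, matrix(c(1L, 1L), 2, 1), t = 1) # at the start arm
  bv <- infer(m, obs, "efe")
  bg <- infer(m, obs, "gfe")
  bmav <- bma_states(bv$pi, bv$s)
  bmag <- bma_states(bg$pi, bg$s)
  for (tau in 2:4)
    expect_gt(tmaze_arm_mass(bmag, tau), tmaze_arm_mass(bmav, tau))
  # mass on the baited arms grows from the proximal to the distal future
  expect_lt(tmaze_arm_mass(bmag, 2), tmaze_arm_mass(bmag, 3))
  expect_lte(tmaze_arm_mass(bmag, 3), tmaze_arm_mass(bmag, 4) + 1e-12)
  # ... at the expense of the cue location at the end of the horizon
  loc4 <- function(bma, tau) sum(bma[c(4, 8), tau])
  expect_lt(loc4(bmag, 4), loc4(bmav, 4))
})
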