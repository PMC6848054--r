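#' Exact evidence by brute-force enumeration
#'
#' Enumerates every (state sequence, policy) pair of a small model and sums
#' the exact joint probability of the observed outcome prefix,
#' `P(o*_1..t) = sum_pi E_pi sum_s P(s_1..T | pi) prod_(tau<=t) P(o*_tau | s_tau)`,
#' in log space with max-shift. Returns the exact log evidence, the exact
#' joint posterior over (sequence, policy), the exact per-time state
#' marginals and the exact policy posterior. Complexity is
#' `n_states^T * n_policies` terms; a configurable cap guards against
#' accidental blow-up.
#'
#' @param model an [mdp_model()].
#' @param obs an [obs_record()].
#' @param t evaluate the evidence of the first `t` observations (defaults to
#'   `obs$t`).
#' @param cap maximum number of enumerated terms (default `1e6`).
#' @return object of class `mdp_oracle`: `log_evidence`, `posterior`
#'   (sequences x policies), `sequences` (T x sequences state indices),
#'   `state_marginals` (states x T), `policy_posterior`, `n_terms`.
#' @export
exact_evidence <- function(model, obs, t = obs$t, cap = 1e6) {
  Tn <- model$T
  n_s <- model$n_states
  n_terms <- n_s^Tn * model$n_policies
  if (n_terms > cap)
    stop_config(sprintf("enumeration size %g exceeds cap %g", n_terms, cap))

  grids <- rev(expand.grid(rev(replicate(Tn, seq_len(n_s), simplify = FALSE))))
  seqs <- t(as.matrix(grids)) # Tn x n_s^Tn
  dimnames(seqs) <- NULL
  n_seq <- ncol(seqs)

  # exact logs (no flooring): -Inf weights vanish in logsumexp
  logw <- matrix(-Inf, n_seq, model$n_policies)
  lA <- lapply(model$A, log)
  lB <- lapply(model$B, log)
  lD <- log(model$D)
  lE <- log(norm1(model$E))
  for (p in seq_len(model$n_policies)) {
    w <- lE[p] + lD[seqs[1, ]]
    for (tau in seq_len(Tn)[-1]) {
      u <- model$U[tau - 1L, p]
      w <- w + lB[[u]][cbind(seqs[tau, ], seqs[tau - 1L, ])]
    }
    if (t > 0) for (tau in seq_len(t)) {
      for (m in seq_len(model$n_modalities))
        w <- w + lA[[m]][obs$o[m, tau], seqs[tau, ]]
    }
    logw[, p] <- w
  }
  log_evidence <- logsumexp(as.numeric(logw))
  post <- exp(logw - log_evidence)

  state_marginals <- matrix(0, n_s, Tn)
  seq_post <- rowSums(post)
  for (tau in seq_len(Tn))
    state_marginals[, tau] <- vapply(seq_len(n_s), function(i)
      sum(seq_post[seqs[tau, ] == i]), numeric(1))

  structure(list(log_evidence = log_evidence, posterior = post,
                 sequences = seqs, state_marginals = state_marginals,
                 policy_posterior = colSums(post), n_terms = n_terms,
                 t = t),
            class = "mdp_oracle")
}

#' @export
print.mdp_oracle <- function(x, digits = 4, ...) {
  cat(sprintf("Exact enumeration over %g terms (t = %d)\n", x$n_terms, x$t))
  cat(sprintf("Log evidence: %.6f  (surprise %.6f)\n",
              x$log_evidence, -x$log_evidence))
  cat("Policy posterior:", paste(round(x$policy_posterior, digits),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Jensen gap between free energy and exact surprise
#'
#' Computes `F - (-ln P(o*))`: the slack in the variational bound on
#' surprise, using the full free energy (including the policy KL term with
#' the fixed-form prior) and the enumeration oracle's exact evidence. The gap
#' is non-negative for any normalised beliefs and vanishes when the
#' mean-field family contains the exact posterior.
#'
#' @param model an [mdp_model()].
#' @param obs an [obs_record()].
#' @param beliefs an `mdp_beliefs` state.
#' @param cap enumeration cap, see [exact_evidence()].
#' @return scalar gap `>= 0` (up to numerical tolerance).
#' @export
jensen_gap <- function(model, obs, beliefs, cap = 1e6) {
  f <- vfe(model, beliefs, obs)
  or <- exact_evidence(model, obs, cap = cap)
  f$total - (-or$log_evidence)
}

#' Exact posterior beliefs for a small model
#'
#' Convenience wrapper turning the oracle's exact posteriors into an
#' `mdp_beliefs` state (policy-conditioned per-time state marginals and the
#' exact policy posterior), e.g. for bound-tightness checks.
#'
#' @inheritParams exact_evidence
#' @return an `mdp_beliefs` object holding exact marginals.
#' @export
oracle_beliefs <- function(model, obs, cap = 1e6) {
  or <- exact_evidence(model, obs, cap = cap)
  b <- init_beliefs(model)
  for (p in seq_len(model$n_policies)) {
    wp <- or$posterior[, p]
    wp <- if (sum(wp) > 0) wp / sum(wp) else rep(1 / length(wp), length(wp))
    for (tau in seq_len(model$T))
      b$s[, tau, p] <- vapply(seq_len(model$n_states), function(i)
        sum(wp[or$sequences[tau, ] == i]), numeric(1))
  }
  b$pi <- norm1(or$policy_posterior)
  b$t <- or$t
  refresh_outcomes(model, b)
}
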