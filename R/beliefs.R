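#' Observation record
#'
#' Holds the outcomes observed so far (one index per modality per past time
#' step) together with the current time `t`. Observations are treated as
#' one-hot vectors in the update algebra.
#'
#' @param model an [mdp_model()].
#' @param outcomes integer matrix (modalities x `t`) of observed outcome
#'   indices, or a vector when the model has a single modality. May be
#'   omitted (with `t = 0`) for the pre-observation prior state.
#' @param t current time; defaults to `ncol(outcomes)`.
#' @return object of class `mdp_obs` with fields `o` (modalities x T integer
#'   matrix, `NA` beyond `t`) and `t`.
#' @export
obs_record <- function(model, outcomes = NULL, t = NULL) {
  n_mod <- model$n_modalities
  o <- matrix(NA_integer_, n_mod, model$T)
  if (!is.null(outcomes)) {
    outcomes <- if (is.matrix(outcomes)) outcomes else
      matrix(as.integer(outcomes), nrow = n_mod)
    if (nrow(outcomes) != n_mod)
      stop_structural("outcomes must have one row per modality")
    if (ncol(outcomes) > model$T) stop_config("more observations than horizon T")
    if (ncol(outcomes) > 0) o[, seq_len(ncol(outcomes))] <- outcomes
  }
  if (is.null(t)) t <- if (is.null(outcomes)) 0L else ncol(outcomes)
  t <- as.integer(t)
  if (t > model$T) stop_config("t exceeds the horizon T")
  for (m in seq_len(n_mod)) {
    seen <- o[m, seq_len(t)]
    if (t > 0 && (any(is.na(seen)) || any(seen < 1L | seen > model$n_outcomes[m])))
      stop_config(sprintf("modality %d outcomes must be valid indices up to t", m))
  }
  structure(list(o = o, t = t), class = "mdp_obs")
}

# fresh belief state: uniform policy-conditioned state beliefs,
# matching predictive outcomes, policy beliefs at the fixed-form prior
init_beliefs <- function(model) {
  s <- array(1 / model$n_states, dim = c(model$n_states, model$T, model$n_policies))
  b <- structure(list(
    s = s,
    o = vector("list", model$n_modalities),
    pi = norm1(model$E), pi0 = norm1(model$E),
    scheme = NULL, t = 0L, trace = NULL, converged = NA
  ), class = "mdp_beliefs")
  refresh_outcomes(model, b)
}

# recompute all predictive outcome arrays from current state beliefs
refresh_outcomes <- function(model, beliefs) {
  for (m in seq_len(model$n_modalities)) {
    om <- array(0, dim = c(model$n_outcomes[m], model$T, model$n_policies))
    for (p in seq_len(model$n_policies))
      om[, , p] <- model$A[[m]] %*% beliefs$s[, , p]
    beliefs$o[[m]] <- om
  }
  beliefs
}

#' Predictive outcome distribution
#'
#' Projects a state belief through the likelihood: `o = A s`, the posterior
#' predictive distribution over outcomes in one modality.
#'
#' @param A likelihood matrix (outcomes x states).
#' @param s_pt normalised state belief vector.
#' @return normalised outcome probability vector.
#' @export
predictive_outcomes <- function(A, s_pt) {
  if (!is_prob_vec(s_pt, 1e-8)) stop_config("state belief must be normalised")
  norm1(as.numeric(as.matrix(A) %*% s_pt))
}

# Transition messages for the state at (policy p, time tau). Two conventions:
# "marginal" (default): log of the propagated belief, fwd = ln(B s_{tau-1}),
#   bwd = ln(B^T s_{tau+1}) — the form used by reference implementations of
#   this scheme; robust for near-deterministic transitions. Structural zeros
#   are kept exact (-Inf logits -> zero posterior mass): flooring them would
#   inject spurious evidence at unreachable states and can break exact
#   symmetries of the model (e.g. between the contexts of the T-maze).
# "vmp": expectation of the log, fwd_i = sum_j s[tau-1, j] ln B[i, j],
#   bwd_i = sum_k s[tau+1, k] ln B[k, i] — the literal mean-field fixed
#   point under the global log-floor; exact coordinate descent on the
#   variational free energy, but over-confident when transitions contain
#   zeros.
# Both use the prior D at tau = 1 and a zero backward message at tau = T.
transition_messages <- function(model, s_p, p, tau,
                                messages = c("marginal", "vmp")) {
  messages <- match.arg(messages)
  exact <- messages == "marginal"
  fwd <- if (tau == 1L) {
    if (exact) log(model$D) else ln(model$D)
  } else {
    u <- model$U[tau - 1L, p]
    if (exact) log(as.numeric(model$B[[u]] %*% s_p[, tau - 1L]))
    else as.numeric(ln(model$B[[u]]) %*% s_p[, tau - 1L])
  }
  bwd <- if (tau == model$T) 0 else {
    u <- model$U[tau, p]
    if (exact) log(as.numeric(t(model$B[[u]]) %*% s_p[, tau + 1L]))
    else as.numeric(t(ln(model$B[[u]])) %*% s_p[, tau + 1L])
  }
  list(fwd = fwd, bwd = bwd)
}

# logits of the variational fixed point (Eq. of motion for state beliefs):
# observed likelihood evidence (past only) plus transition messages
state_logits_vfe <- function(model, beliefs, obs, p, tau,
                             messages = "marginal") {
  msg <- transition_messages(model, beliefs$s[, , p, drop = FALSE][, , 1],
                             p, tau, messages)
  lg <- if (messages == "marginal") log else ln
  lik <- 0
  if (tau <= obs$t)
    for (m in seq_len(model$n_modalities))
      lik <- lik + lg(model$A[[m]][obs$o[m, tau], ])
  lik + msg$fwd + msg$bwd
}

# logits under the generalised objective: for the future the likelihood
# evidence is replaced by the negative likelihood entropy plus a pull of
# predictive outcomes toward preferences, A^T (ln C - ln o)
state_logits_gfe <- function(model, beliefs, obs, p, tau,
                             messages = "marginal") {
  if (tau <= obs$t)
    return(state_logits_vfe(model, beliefs, obs, p, tau, messages))
  msg <- transition_messages(model, beliefs$s[, , p, drop = FALSE][, , 1],
                             p, tau, messages)
  extra <- 0
  for (m in seq_len(model$n_modalities)) {
    o_pt <- predictive_outcomes(model$A[[m]], beliefs$s[, tau, p])
    extra <- extra + likelihood_neg_entropy(model$A[[m]]) +
      as.numeric(t(model$A[[m]]) %*% (model$C[[m]][, tau] - ln(o_pt)))
  }
  extra + msg$fwd + msg$bwd
}

#' Fixed-point state-belief update (variational scheme)
#'
#' Updates the policy-conditioned belief about the hidden state at one time
#' step to its mean-field fixed point: a softmax of observed log-likelihood
#' evidence (for past/present steps) plus forward and backward transition
#' messages. The initial step uses the prior `D` as its forward message; the
#' final step has no backward message.
#'
#' @param model an [mdp_model()].
#' @param beliefs an `mdp_beliefs` state (see [infer()]).
#' @param obs an [obs_record()].
#' @param p policy index.
#' @param tau time index in `1..T`.
#' @param messages transition-message convention: `"marginal"` (default, log
#'   of the propagated belief `ln(B s)`, as used by reference
#'   implementations) or `"vmp"` (expectation of the log, the literal
#'   mean-field fixed point; exact coordinate descent on the free energy but
#'   over-confident when transitions contain zeros).
#' @return updated (normalised) state belief vector for `(p, tau)`.
#' @export
update_states_vfe <- function(model, beliefs, obs, p, tau,
                              messages = c("marginal", "vmp")) {
  messages <- match.arg(messages)
  if (tau < 1L || tau > model$T) stop_config("tau out of range")
  check_beliefs_normalised(beliefs, p)
  softmax(state_logits_vfe(model, beliefs, obs, p, tau, messages))
}

#' Fixed-point state-belief update (generalised scheme)
#'
#' Identical to [update_states_vfe()] for observed time steps. For future
#' steps the likelihood evidence is replaced by the negative likelihood
#' entropy (penalising ambiguous states) and a term `A^T (ln C - ln o)`
#' pulling beliefs toward states whose predicted outcomes match preferences
#' — the optimistic distortion. Predictive outcomes are recomputed from the
#' current state belief, so the fixed point is self-consistent.
#'
#' @inheritParams update_states_vfe
#' @return updated (normalised) state belief vector for `(p, tau)`.
#' @export
update_states_gfe <- function(model, beliefs, obs, p, tau,
                              messages = c("marginal", "vmp")) {
  messages <- match.arg(messages)
  if (tau < 1L || tau > model$T) stop_config("tau out of range")
  check_beliefs_normalised(beliefs, p)
  softmax(state_logits_gfe(model, beliefs, obs, p, tau, messages))
}

check_beliefs_normalised <- function(beliefs, p) {
  sums <- colSums(beliefs$s[, , p, drop = FALSE][, , 1, drop = FALSE])
  if (any(abs(sums - 1) > 1e-8))
    stop_config("state beliefs must be normalised before updating")
}

#' One gradient-flow step on state beliefs
#'
#' A biologically plausible alternative to the discrete fixed-point update:
#' an Euler step on unnormalised log-beliefs toward the fixed-point logits.
#' Stationary points coincide with the fixed-point solutions; `rate = 1`
#' recovers the discrete update and `rate = 0` is the identity.
#'
#' @inheritParams update_states_vfe
#' @param rate step size in (0, 1].
#' @param scheme `"vfe"` or `"gfe"` target logits.
#' @return updated state belief vector for `(p, tau)`.
#' @export
gradient_flow_step <- function(model, beliefs, obs, p, tau, rate,
                               scheme = c("vfe", "gfe"),
                               messages = c("marginal", "vmp")) {
  scheme <- match.arg(scheme)
  messages <- match.arg(messages)
  if (rate < 0) stop_config("rate must be >= 0")
  logits <- if (scheme == "vfe")
    state_logits_vfe(model, beliefs, obs, p, tau, messages)
  else state_logits_gfe(model, beliefs, obs, p, tau, messages)
  target <- lsoftmax(logits)
  v <- pmax(log(beliefs$s[, tau, p]), -700)
  softmax(ifelse(is.infinite(target), target, v + rate * (target - v)))
}

#' Policy-posterior update
#'
#' Softmax combination of the fixed-form policy prior with per-policy free
#' energies: under the expected-free-energy scheme
#' `pi = softmax(ln E - G - F)`; under the generalised scheme
#' `pi = softmax(ln E - GG)` where `GG` is the per-policy generalised free
#' energy (which already contains the past variational terms).
#'
#' @param E fixed-form prior over policies.
#' @param F_p per-policy variational free energy (ignored for `"gfe"`).
#' @param G_p per-policy expected free energy (`"efe"`) or generalised free
#'   energy (`"gfe"`).
#' @param scheme `"efe"` or `"gfe"`.
#' @return normalised policy posterior vector.
#' @export
update_policies <- function(E, F_p, G_p, scheme = c("efe", "gfe")) {
  scheme <- match.arg(scheme)
  if (length(E) != length(G_p) || (scheme == "efe" && length(F_p) != length(G_p)))
    stop_structural("policy vectors must share the policy dimension")
  if (scheme == "efe") softmax(ln(E) - F_p - G_p) else softmax(ln(E) - G_p)
}

#' Bayesian model average of state beliefs
#'
#' Averages policy-conditioned state beliefs under the policy posterior:
#' `sbar_tau = sum_pi pi * s_(pi,tau)`. This is the quantity plotted in
#' belief rasters.
#'
#' @param pi normalised policy posterior.
#' @param s state belief array (states x T x policies) or matrix
#'   (states x policies) for a single time step.
#' @return matrix (states x T) of averaged beliefs (or a vector for matrix
#'   input), columns normalised.
#' @export
bma_states <- function(pi, s) {
  if (!is_prob_vec(pi, 1e-8)) stop_config("pi must be normalised")
  if (is.matrix(s)) return(norm1(as.numeric(s %*% pi)))
  out <- matrix(0, dim(s)[1], dim(s)[2])
  for (p in seq_along(pi)) out <- out + pi[p] * s[, , p]
  apply(out, 2, norm1)
}

#' Infer posterior beliefs by mean-field fixed-point iteration
#'
#' Sweeps the state-belief fixed-point updates forward then backward in time
#' for every policy, refreshes predictive outcomes, recomputes the free
#' energies and the policy posterior, and repeats until the maximum belief
#' change falls below `tol` or `max_iters` sweeps are reached. Under
#' `scheme = "efe"` states follow the variational update and policies the
#' expected-free-energy posterior `softmax(ln E - F - G)`; under
#' `scheme = "gfe"` states follow the generalised update and policies
#' `softmax(ln E - GG)`.
#'
#' @param model an [mdp_model()].
#' @param obs an [obs_record()] with outcomes up to the current time.
#' @param scheme `"efe"` or `"gfe"`.
#' @param init optional `mdp_beliefs` to warm-start from (online use).
#' @param tol convergence tolerance on the max-norm belief change
#'   (default 1e-6).
#' @param max_iters maximum sweeps (default 100); non-convergence is flagged
#'   in the trace, not an error.
#' @param messages transition-message convention, see [update_states_vfe()].
#' @param rate damping rate in (0, 1] for the state updates: each touch moves
#'   log-beliefs a fraction `rate` toward the fixed-point logits (`1` is the
#'   full discrete update). Defaults to `1` for `"efe"` and `0.5` for
#'   `"gfe"`, whose self-consistent future update overshoots under full
#'   steps; the fixed points are identical for any positive rate.
#' @return an object of class `mdp_beliefs`: state beliefs `s`
#'   (states x T x policies), predictive outcomes `o` (per modality), policy
#'   posterior `pi` and prior `pi0`, the final free-energy breakdown `fe`,
#'   and a per-sweep `trace` (max change, total free energy).
#' @export
infer <- function(model, obs, scheme = c("efe", "gfe"), init = NULL,
                  tol = 1e-6, max_iters = 100L,
                  messages = c("marginal", "vmp"), rate = NULL) {
  scheme <- match.arg(scheme)
  messages <- match.arg(messages)
  if (obs$t > model$T) stop_config("t exceeds the horizon")
  if (is.null(rate)) rate <- if (scheme == "efe") 1 else 0.5
  b <- if (is.null(init)) init_beliefs(model) else init
  logits_fun <- if (scheme == "efe") state_logits_vfe else state_logits_gfe

  trace <- data.frame(iter = integer(), delta = numeric(), total = numeric())
  trace_F <- NULL # per-sweep per-policy variational free energies
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    s_old <- b$s
    pi_old <- b$pi
    for (p in seq_len(model$n_policies)) {
      for (tau in c(seq_len(model$T), rev(seq_len(model$T)))) {
        target <- lsoftmax(logits_fun(model, b, obs, p, tau, messages))
        v <- if (rate == 1) target else {
          # damp in log space; keep structural zeros exact, avoid -Inf - -Inf
          v0 <- pmax(log(b$s[, tau, p]), -700)
          ifelse(is.infinite(target), target, v0 + rate * (target - v0))
        }
        b$s[, tau, p] <- softmax(v)
      }
    }
    b <- refresh_outcomes(model, b)

    fv <- vfe(model, b, obs)
    if (scheme == "efe") {
      fe <- efe(model, b, obs$t)
      b$pi <- update_policies(model$E, fv$F_p, fe$G_p, "efe")
      b$pi0 <- softmax(ln(model$E) - fe$G_p)
      # Lyapunov audit: full free energy with the EFE-informed policy prior
      total <- sum(b$pi * fv$F_p) + kl_cat(b$pi, b$pi0)
      fe$F_pt <- fv$F_pt; fe$F_p <- fv$F_p
    } else {
      fe <- gfe(model, b, obs)
      b$pi <- update_policies(model$E, NULL, fe$GG_p, "gfe")
      b$pi0 <- softmax(ln(model$E) - fe$G_future_p)
      total <- sum(b$pi * fe$GG_p) + kl_cat(b$pi, norm1(model$E))
      fe$F_pt <- fv$F_pt; fe$F_p <- fv$F_p
    }
    delta <- max(abs(b$s - s_old), abs(b$pi - pi_old))
    trace <- rbind(trace, data.frame(iter = it, delta = delta, total = total))
    trace_F <- rbind(trace_F, fv$F_p)
    if (delta < tol) { converged <- TRUE; break }
  }
  b$fe <- fe
  b$scheme <- scheme
  b$messages <- messages
  b$t <- obs$t
  b$trace <- trace
  b$trace_F <- trace_F
  b$converged <- converged
  b
}

#' @export
print.mdp_beliefs <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior beliefs (%s scheme), t = %d, %s after %d sweep(s)\n",
              toupper(x$scheme %||% "?"), x$t,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              if (is.null(x$trace)) 0L else nrow(x$trace)))
  cat("Policy posterior:\n")
  print(round(x$pi, digits))
  invisible(x)
}

#' @export
summary.mdp_beliefs <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  cat("\nBayesian model average of state beliefs (states x time):\n")
  print(round(bma_states(object$pi, object$s), digits))
  if (!is.null(object$fe)) {
    cat("\nPer-policy free energies:\n")
    tab <- data.frame(policy = seq_along(object$pi), F = object$fe$F_p)
    if (!is.null(object$fe$G_p)) tab$G <- object$fe$G_p
    if (!is.null(object$fe$GG_p)) tab$GG <- object$fe$GG_p
    print(round(tab, digits), row.names = FALSE)
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
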