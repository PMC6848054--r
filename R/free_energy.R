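#' Variational free energy breakdown
#'
#' Evaluates the mean-field variational free energy per policy and time step,
#' `F_pt = -E_Q[ [tau<=t] ln P(o|s) + ln P(s_tau|s_tau-1, pi) - ln Q(s_tau|pi) ]`,
#' with the prior `D` supplying the transition term at `tau = 1`. For future
#' steps (`tau > t`) the term reduces to a complexity cost — the expected KL
#' divergence of beliefs from transition-propagated beliefs — and is
#' non-negative. Also returns per-policy totals and the full free energy
#' `total = E_pi[F_p] + KL[pi || prior_pi]`.
#'
#' @param model an [mdp_model()].
#' @param beliefs an `mdp_beliefs` state (see [infer()]).
#' @param obs an [obs_record()].
#' @param prior_pi prior over policies for the total's KL term; defaults to
#'   the fixed-form prior `E`.
#' @return object of class `mdp_fe` with fields `F_pt` (T x policies), `F_p`,
#'   `total`, `t`.
#' @export
vfe <- function(model, beliefs, obs, prior_pi = NULL) {
  if (obs$t > model$T) stop_config("t exceeds the horizon")
  Tn <- model$T
  F_pt <- matrix(0, Tn, model$n_policies)
  for (p in seq_len(model$n_policies)) {
    s_p <- beliefs$s[, , p, drop = FALSE][, , 1, drop = FALSE]
    dim(s_p) <- c(model$n_states, Tn)
    for (tau in seq_len(Tn)) {
      s <- s_p[, tau]
      lik <- 0
      if (tau <= obs$t)
        for (m in seq_len(model$n_modalities))
          lik <- lik + sum(s * ln(model$A[[m]][obs$o[m, tau], ]))
      trans <- if (tau == 1L) sum(s * ln(model$D)) else {
        u <- model$U[tau - 1L, p]
        sum(s * as.numeric(ln(model$B[[u]]) %*% s_p[, tau - 1L]))
      }
      F_pt[tau, p] <- -lik - trans + sum(s * ln(s))
    }
  }
  F_p <- colSums(F_pt)
  prior_pi <- if (is.null(prior_pi)) norm1(model$E) else prior_pi
  total <- sum(beliefs$pi * F_p) + kl_cat(beliefs$pi, prior_pi)
  structure(list(kind = "vfe", t = obs$t, F_pt = F_pt, F_p = F_p,
                 total = total),
            class = "mdp_fe")
}

#' Expected free energy breakdown
#'
#' Evaluates the expected free energy of each policy over future time steps
#' (`tau > t`) from predictive state and outcome beliefs, in both of its
#' decompositions: `G = risk + ambiguity`, where risk is the KL divergence of
#' predicted from preferred outcomes and ambiguity the expected likelihood
#' entropy under state beliefs, and `G = -epistemic - extrinsic`, where
#' epistemic value is the mutual information between states and outcomes
#' under the predictive joint `P(o|s) Q(s|pi)` and extrinsic value the
#' expected log preference of predicted outcomes. Modalities contribute
#' additively.
#'
#' @param model an [mdp_model()].
#' @param beliefs an `mdp_beliefs` state with predictive outcomes `o = A s`.
#' @param t current time; contributions exist only for `tau > t`.
#' @return object of class `mdp_fe` with `G_pt`, `G_p` and part arrays
#'   `risk`, `ambiguity`, `epistemic`, `extrinsic` (T x policies, zero rows
#'   for `tau <= t`).
#' @export
efe <- function(model, beliefs, t) {
  if (t > model$T) stop_config("t exceeds the horizon")
  Tn <- model$T
  zero <- matrix(0, Tn, model$n_policies)
  risk <- ambiguity <- epistemic <- extrinsic <- zero
  H_m <- lapply(model$A, likelihood_neg_entropy)
  for (p in seq_len(model$n_policies)) {
    for (tau in seq_len(Tn)) {
      if (tau <= t) next
      s <- beliefs$s[, tau, p]
      for (m in seq_len(model$n_modalities)) {
        o <- predictive_outcomes(model$A[[m]], s)
        cln <- model$C[[m]][, tau]
        risk[tau, p] <- risk[tau, p] + sum(o * (ln(o) - cln))
        ambiguity[tau, p] <- ambiguity[tau, p] - sum(s * H_m[[m]])
        epistemic[tau, p] <- epistemic[tau, p] +
          marginal_outcome_entropy(o) + sum(s * H_m[[m]])
        extrinsic[tau, p] <- extrinsic[tau, p] + sum(o * cln)
      }
    }
  }
  G_pt <- risk + ambiguity
  structure(list(kind = "efe", t = t, G_pt = G_pt, G_p = colSums(G_pt),
                 risk = risk, ambiguity = ambiguity,
                 epistemic = epistemic, extrinsic = extrinsic),
            class = "mdp_fe")
}

#' Generalised free energy breakdown
#'
#' Evaluates the generalised free energy, in which future outcomes are latent
#' variables with posterior beliefs: `GG_p = sum_(tau<=t) F_pt + ln(n_o) +
#' sum_(tau>t) GG_future_pt`. Observed steps contribute their variational
#' terms plus the flat past outcome-prior constant (`ln` of the number of
#' outcomes, per modality), which is policy-independent and cancels in every
#' policy softmax. Future steps contribute the free energy of the expected
#' future, decomposed as `complexity + risk + ambiguity` and equivalently as
#' `complexity - mutual_information - extrinsic`. Complexity is the
#' divergence of state beliefs from transition-propagated beliefs under the
#' expectation-of-log convention, making the generalised objective sum
#' exactly the same terms as the variational plus expected free energies.
#'
#' @param model an [mdp_model()].
#' @param beliefs an `mdp_beliefs` state.
#' @param obs an [obs_record()].
#' @return object of class `mdp_fe` with `GG_pt`, `GG_p`, the future part
#'   `G_future_pt`/`G_future_p`, part arrays `complexity`, `risk`,
#'   `ambiguity`, `mutual_information`, `extrinsic`, and the full objective
#'   `total = E_pi[GG_p] + KL[pi || E]`.
#' @export
gfe <- function(model, beliefs, obs) {
  t <- obs$t
  Tn <- model$T
  fv <- vfe(model, beliefs, obs)
  past_const <- sum(log(model$n_outcomes)) # flat outcome prior per modality
  zero <- matrix(0, Tn, model$n_policies)
  complexity <- risk <- ambiguity <- mi <- extrinsic <- zero
  H_m <- lapply(model$A, likelihood_neg_entropy)

  for (p in seq_len(model$n_policies)) {
    s_p <- beliefs$s[, , p, drop = FALSE][, , 1, drop = FALSE]
    dim(s_p) <- c(model$n_states, Tn)
    for (tau in seq_len(Tn)) {
      if (tau <= t) next
      s <- s_p[, tau]
      # complexity: E_{Q(s_{tau-1})} sum_j KL[Q(s_tau) || B(., j)]
      trans <- if (tau == 1L) sum(s * ln(model$D)) else {
        u <- model$U[tau - 1L, p]
        sum(s * as.numeric(ln(model$B[[u]]) %*% s_p[, tau - 1L]))
      }
      complexity[tau, p] <- sum(s * ln(s)) - trans
      for (m in seq_len(model$n_modalities)) {
        o <- predictive_outcomes(model$A[[m]], s)
        cln <- model$C[[m]][, tau]
        risk[tau, p] <- risk[tau, p] + sum(o * (ln(o) - cln))
        ambiguity[tau, p] <- ambiguity[tau, p] - sum(s * H_m[[m]])
        mi[tau, p] <- mi[tau, p] +
          marginal_outcome_entropy(o) + sum(s * H_m[[m]])
        extrinsic[tau, p] <- extrinsic[tau, p] + sum(o * cln)
      }
    }
  }
  G_future_pt <- complexity + risk + ambiguity
  GG_pt <- G_future_pt
  if (t > 0) {
    past <- seq_len(t)
    GG_pt[past, ] <- fv$F_pt[past, , drop = FALSE] + past_const
  }
  GG_p <- colSums(GG_pt)
  total <- sum(beliefs$pi * GG_p) + kl_cat(beliefs$pi, norm1(model$E))
  structure(list(kind = "gfe", t = t,
                 GG_pt = GG_pt, GG_p = GG_p,
                 G_future_pt = G_future_pt, G_future_p = colSums(G_future_pt),
                 complexity = complexity, risk = risk, ambiguity = ambiguity,
                 mutual_information = mi, extrinsic = extrinsic,
                 past_const = past_const, total = total),
            class = "mdp_fe")
}

#' Entropy of a predictive outcome distribution
#'
#' Shannon entropy `H[Q(o|pi)] = -sum o ln o` of a normalised predictive
#' outcome vector; non-negative, zero for one-hot vectors, and invariant to
#' permutation of outcome labels.
#'
#' @param o_p normalised outcome probability vector.
#' @return non-negative scalar.
#' @export
marginal_outcome_entropy <- function(o_p) {
  if (!is_prob_vec(o_p, 1e-8)) stop_config("outcome vector must be normalised")
  -sum(o_p * ln(o_p))
}

#' Flatten a free-energy breakdown to a long table
#'
#' @param x an `mdp_fe` object from [vfe()], [efe()] or [gfe()].
#' @param ... unused.
#' @return data frame with columns `policy`, `tau`, `term`, `value`.
#' @export
as.data.frame.mdp_fe <- function(x, ...) {
  mats <- Filter(function(f) is.matrix(x[[f]]),
                 setNames(nm = names(x)))
  rows <- lapply(mats, function(f) {
    m <- x[[f]]
    data.frame(policy = rep(seq_len(ncol(m)), each = nrow(m)),
               tau = rep(seq_len(nrow(m)), ncol(m)),
               term = f, value = as.numeric(m))
  })
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' @export
print.mdp_fe <- function(x, digits = 4, ...) {
  cat(sprintf("Free energy breakdown (%s), t = %d\n", x$kind, x$t))
  tot <- switch(x$kind, vfe = x$F_p, efe = x$G_p, gfe = x$GG_p)
  tab <- data.frame(policy = seq_along(tot), value = round(tot, digits))
  names(tab)[2] <- switch(x$kind, vfe = "F", efe = "G", gfe = "GG")
  print(tab, row.names = FALSE)
  if (!is.null(x$total)) cat(sprintf("Total: %.6g\n", x$total))
  invisible(x)
}
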