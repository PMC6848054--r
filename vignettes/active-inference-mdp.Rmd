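---
title: "Active inference in discrete state spaces: models, objectives and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active inference in discrete state spaces: models, objectives and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimdp)
```

## The generative model

`aimdp` works with categorical generative models of partially observed
Markov decision processes. A model is the tuple `(A, B, C, D, E, U, T)`:

* `A` — one likelihood matrix per outcome modality; column `j` is the
  outcome distribution in state `j`. Modalities are conditionally
  independent given the state, so their log-likelihoods, entropies, risks
  and information terms add.
* `B` — one transition matrix per action; column `j` is the next-state
  distribution from state `j` under that action.
* `C` — log-preferences over outcomes per modality and time step, stored so
  that `exp(C)` is a distribution: preferences are a prior over outcomes,
  and "reward" is nothing but log prior probability.
* `D` — prior over the initial hidden state; `E` — fixed-form prior over
  policies.
* `U` — the policy set: `T - 1` rows of action indices, one column per
  policy. A policy is an action sequence treated as a latent variable.

Hidden states form a single joint factor. For the T-maze this is the
4 locations x 2 contexts = 8 joint states; factorised (mean-field across
factors) state spaces are out of scope. Time is 1-based; the action in row
`tau` of `U` moves the world from step `tau` to `tau + 1`.

The approximate posterior is mean-field across time and policies:
`Q(s_1..T, pi) = Q(pi) prod_tau Q(s_tau | pi)`, with categorical sufficient
statistics `s_ptau` (states), `o_ptau = A s_ptau` (predicted outcomes) and
`pi` (policies).

## Two objectives

**Variational free energy (`vfe`)** is a function of the outcomes observed
so far and a functional of beliefs:

```
F_ptau = -E_Q[ [tau<=t] ln P(o_tau|s_tau) + ln P(s_tau|s_tau-1, pi) - ln Q(s_tau|pi) ]
```

Future steps contribute a non-negative complexity cost — the expected
divergence of beliefs from transition-propagated beliefs. By Jensen's
inequality the total `F = E_pi[F_p] + KL[Q(pi)||P(pi)]` upper-bounds
surprise, `F >= -ln P(o*)`; the package's enumeration oracle
(`exact_evidence`, `jensen_gap`) certifies this bound exactly on small
models.

**Expected free energy (`efe`)** scores each policy's future under the
predictive joint `P(o|s) Q(s|pi)`:

```
G_ptau = risk + ambiguity = KL[Q(o|pi) || exp(C)] + E_Q(s)[H[P(o|s)]]
       = -epistemic - extrinsic
```

Policies follow `Q(pi) = softmax(ln E - G_p - F_p)`: agents prefer policies
expected to realise preferred outcomes (extrinsic value) and to resolve
uncertainty (epistemic value, the state–outcome mutual information).

**Generalised free energy (`gfe`)** instead treats future outcomes as latent
variables: `Q(o_tau|s_tau)` is a delta on the datum for `tau <= t` and the
likelihood `P(o_tau|s_tau)` for `tau > t`, and the outcome prior `exp(C)`
becomes part of the generative model. One functional then drives everything:

```
GG_p = sum_{tau<=t} [ F_ptau + ln(n_outcomes) ] + sum_{tau>t} GG_future_ptau
GG_future_ptau = complexity + risk + ambiguity
               = complexity - mutual_information - extrinsic
Q(pi) = softmax(ln E - GG_p)
```

For observed steps the outcome prior is flat, so the generalised functional
reduces to the variational one up to a policy-independent constant
(`ln` of the number of outcomes per modality per observed step); we keep the
constant explicit so the reduction is visible, and it cancels in every
policy softmax.

Two conventions exist for the complexity term (the expectation can sit
inside or outside the logarithm of the transition probabilities). We use the
expectation-of-log reading throughout the free-energy *evaluations*, because
it is the one under which the generalised functional sums exactly the same
terms as the variational-plus-expected combination, making
`softmax(ln E - F - G) = softmax(ln E - GG)` an exact identity for shared
beliefs — the two schemes then differ only through the beliefs their state
updates produce. The mixture-inside-log reading would break that identity.
One consequence is accepted: the claim that the future part is an upper
bound on expected surprise is not guaranteed term-by-term under this
convention and is not asserted anywhere.

## Belief updates and the message convention

Each state belief is updated to a softmax of its Markov blanket:
likelihood evidence (observed steps), a forward transition message, and a
backward transition message; the generalised scheme replaces the likelihood
term for future steps by the negative likelihood entropy plus the optimism
pull `A^T (ln C - ln o)`, with the predicted outcome `o` recomputed from the
current belief (a self-consistent fixed point).

The transition messages come in two conventions, exposed as the `messages`
argument of `infer()` and the update functions:

* `"marginal"` (default): `ln(B s_prev)` and `ln(B^T s_next)` — the log of
  the propagated belief, as in the reference implementations of this family
  of schemes. Structural zeros are kept exact: an impossible state gets
  `-Inf` logits and exactly zero mass.
* `"vmp"`: the literal mean-field fixed point, `(ln B) s` with the global
  log-floor. These updates are exact coordinate minimisers of the
  variational free energy, which makes free-energy descent across sweeps an
  exact invariant (we test it at 1e-8), but they are over-confident when
  transitions contain zeros: belief-weighted sums of floored `ln B` penalise
  any mixture over parallel deterministic chains by up to 16 nats per step,
  so the posterior collapses onto one chain even when the evidence is
  symmetric. On the T-maze this collapse invents certainty about the context
  after an uninformative cue and destroys epistemic foraging; that is why it
  is not the default.

Two numerical choices matter here and were made deliberately:

* **Log-floor.** All free-energy evaluations use `ln(max(x, exp(-16)))`, so
  deterministic and absorbing structures give finite energies. In the
  *marginal* messages, however, structural zeros are not floored: flooring
  them injects spurious likelihood evidence at unreachable states (breaking,
  for example, the exact symmetry between the two T-maze contexts at the
  ambiguous cue) and, under the generalised update, lets the preference pull
  (bounded by 16 nats via the floored `-ln o`) balance the 16-nat transition
  penalty, teleporting belief mass to unreachable-but-preferred states.
* **Damping.** `infer()` iterates forward–backward sweeps over all policies
  until the max-norm belief change is below `tol` (1e-6) or `max_iters`
  (100) sweeps. The variational updates take full steps; the generalised
  updates use a gradient step of `rate = 0.5` on log-beliefs toward the same
  fixed points (full steps overshoot the self-consistent `ln o` term and
  oscillate). `gradient_flow_step()` exposes the same continuous-flow update
  for any rate; its stationary points coincide with the discrete fixed
  points, which we verify by running both to convergence.

Beliefs are initialised uniform and warm-started between observations
(online evidence accumulation). Sweeps run ascending then descending in
time; policies are independent given the state updates. Softmaxes use
max-subtraction; an all-`-Inf` logit vector (an observation impossible under
a policy) falls back to uniform beliefs — such policies receive essentially
zero posterior weight, so the fallback only affects bookkeeping.

## The T-maze fixture

`build_tmaze()` constructs the standard epistemic-foraging task: start arm
(location 1) with an ambiguous 50/50 cue, absorbing baited arms (2 left,
3 right), a cue location (4) whose conditioned stimulus deterministically
signals the context, the unconditioned stimulus delivered with `p_us = 0.9`
in the context-correct arm, `1 - p_us` in the other (the symmetric minimal
completion), uniform context prior, and the 10 distinct policies over two
free "go to location" moves with a forced stay thereafter.

Default cue preferences are `US = 1.5, CS = 1, NS = -3` (location
preferences flat). Only the ordering US > CS > NS is fixed by the task; the
magnitudes are a genuine design choice, and they are *constrained from both
sides* by the requirement that the two schemes reproduce the canonical
behaviour:

* Under the generalised scheme, belief optimisation may collapse the
  context optimistically ("the reward is wherever I am going"), at a
  one-off complexity cost of `ln 2`. Cue-seeking survives only if the cue's
  preference beats the risky-arm gamble:
  `c_CS > p_us c_US + (1 - p_us) c_NS` (up to policy-aggregation slack).
* Under the expected-free-energy scheme, the move from the cue to the
  known-correct arm requires the opposite inequality with an ambiguity
  margin `H(p_us)`.

Strong preference spreads (e.g. US = 3, CS = 1, NS = -3) violate the first
condition: the generalised agent then skips the cue and gambles on an arm.
The defaults sit in the joint window, verified for both schemes, both
contexts and a range of seeds. This sensitivity is itself a finding worth
knowing about: the equivalence of the two schemes' *behaviour* (as opposed
to their policy-posterior algebra) holds only for moderate preferences.

```{r tmaze, eval = FALSE}
maze <- build_tmaze()
run_trial(maze, scheme = "efe", seed = 1, true_initial_state = 1)$actions
# goto4, then the cued arm, then stay — same under scheme = "gfe"
```

### The optimistic distortion

At `t = 1` both agents plan to visit the cue. But the generalised agent's
beliefs about the *distal* future are pulled toward the rewarding arms: the
Bayesian-model-average mass on locations 2 and 3 at `tau = 2` and `tau = 4`
strictly exceeds the variational agent's, grows from `tau = 2` to
`tau = 3`, and the mass on the cue location at the end of the horizon
shrinks. One published detail is *not* reproduced at convergence: a strict
increase from `tau = 3` to `tau = 4`. With this policy set (absorbing arms,
forced stay after the second action) a policy occupies an arm at `tau = 3`
exactly when it does at `tau = 4`, so any Bayesian model average over exact
fixed points is *equal* at the two times; a strict increase there can only
arise from floored-log leakage through structurally impossible transitions,
i.e. from numerical transients rather than from the model. We keep the
exact-reachability behaviour and document the equality.

## Scope of the synthetic-model generator

`random_model()` draws flat-Dirichlet stochastic arrays, Gaussian preference
logits and uniform random policy arrays — dense, well-conditioned models
with no zeros. It emulates the *algebraic* setting of the theory (arbitrary
categorical POMDPs) and is the right fixture for the bound, identity and
fixed-point tests, because the enumeration oracle is exact there. It does
not emulate the structured sparsity of real tasks (deterministic mappings,
absorbing states, ambiguous cues); those regimes are covered by the T-maze
fixture, and conclusions from random-model tests do not automatically
transfer to them — the message-convention analysis above is exactly a case
where sparse structure changes the numerics qualitatively.

Model sizes in the test and acceptance suites (2–4 states, 1–4 policies,
horizons 1–3, batches of 25–100 models) keep the brute-force oracle exact
and the whole suite desk-scale; they were chosen as the smallest sizes that
exercise every term (multiple modalities, multiple policies, past and future
steps).

## Known limitations

* Single joint state factor; no learning of `A`, `B` or `D` (no Dirichlet
  updating), no habits, no precision over policies, no hierarchical or
  continuous extensions.
* The mean-field family cannot represent correlated mixtures of state
  chains, so inferred marginals match the exact posterior only where the
  family contains it (one observed step, or a degenerate chain); elsewhere
  the variational optimum is over-confident relative to the exact marginals
  — by design of the approximation, not a bug.
* Under the default marginal messages, free-energy descent across sweeps is
  approximate (the updates are not exact coordinate minimisers of the
  evaluated functional); exact monotone descent holds under
  `messages = "vmp"`, where we assert it.
* The generalised scheme's behaviour depends on preference magnitudes (see
  the inequality above); users changing `preference_logits` should re-check
  which side of the window they are on.
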