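# aimdp — active inference for discrete Markov decision processes

`aimdp` implements discrete-state active inference: agents that perceive and
act by minimising a free-energy functional under a categorical generative
model of a partially observed Markov decision process. It is aimed at
computational neuroscientists and behavioural modellers who want a small,
fully inspectable engine for planning-as-inference experiments — every
belief, message and free-energy term is a plain R vector you can print.

The package supports the two objective functions used in this literature and
lets you compare them on the same task:

* **Variational free energy with an expected-free-energy policy prior**
  ("efe" scheme). State beliefs minimise the variational free energy

  `F_π = Σ_τ −E_Q[ [τ≤t]·ln P(o_τ|s_τ) + ln P(s_τ|s_τ−1,π) − ln Q(s_τ|π) ]`,

  and policies follow `Q(π) = σ(ln E − G_π − F_π)`, where the expected free
  energy `G_π = Σ_{τ>t} risk + ambiguity = Σ_{τ>t} −epistemic − extrinsic`
  scores each policy's predicted future.

* **Generalised free energy** ("gfe" scheme), in which future outcomes are
  latent variables with posterior beliefs. A single functional
  `𝓕_π = Σ_{τ≤t} F_πτ + Σ_{τ>t} 𝒢_πτ` drives both state updating and policy
  selection (`Q(π) = σ(ln E − 𝓕_π)`); the free energy of the expected future
  decomposes as `𝒢 = complexity + risk + ambiguity`. Prior preferences now
  sit inside the generative model, so beliefs about future states are pulled
  toward states that generate preferred outcomes — an optimistic distortion
  of the believed trajectory.

A generative model is the tuple `(A, B, C, D, E, U, T)`: per-modality
likelihood arrays, per-action transition arrays, log-preferences over
outcomes, priors over initial states and policies, and the policy set. The
classic T-maze foraging task (ambiguous start, instructive cue location,
two absorbing reward arms, two contexts) ships as a built-in fixture, a
brute-force enumeration oracle provides exact evidence and posteriors on
small models, and a command line interface reproduces the simulation tables.

## Worked example

```r
library(aimdp)

maze <- build_tmaze()          # 8 joint states (4 locations x 2 contexts)
maze
#> Generative model: 8 states, 4 action(s), 10 policies, horizon T = 4
#> Outcome modalities: 4 outcomes, 4 outcomes
#> States: loc1/ctx1, loc2/ctx1, loc3/ctx1, loc4/ctx1, loc1/ctx2, ...

trial <- run_trial(maze, scheme = "gfe", seed = 1, true_initial_state = 1)
trial
#> Trial (GFE scheme, seed 1): T = 4
#> True states:   loc1/ctx1 -> loc4/ctx1 -> loc2/ctx1 -> loc2/ctx1
#> Actions:       goto4, goto2, goto2
#> Observations[1]: loc1, loc4, loc2, loc2
#> Observations[2]: CS-blue, CS-blue, US, US
```

The agent first visits the unrewarding cue location 4 (the cue there reveals
the context, so this move has high epistemic value), reads the conditioned
stimulus, and only then collects the reward in the cued arm — the
epistemic-then-pragmatic sequence. The same happens under `scheme = "efe"`.

The two schemes differ in what they believe about the future. At the first
time step, before any action:

```r
obs <- obs_record(maze, matrix(c(1, 1), 2, 1), t = 1)  # loc1, CS-blue
b_efe <- infer(maze, obs, "efe")
b_gfe <- infer(maze, obs, "gfe")
arm_mass <- function(b, tau)
  sum(bma_states(b$pi, b$s)[c(2, 3, 6, 7), tau])
round(c(efe = arm_mass(b_efe, 4), gfe = arm_mass(b_gfe, 4)), 3)
#>   efe   gfe
#> 0.027 1.000
```

The expected-free-energy agent mostly believes it will stay at the cue
location, while the generalised agent believes it will end the trial in one
of the (potentially rewarding) arms: its preferences distort beliefs about
the future trajectory. `plot(trial)` draws the Bayesian-model-average belief
rasters (states x represented time, one panel per observation time).

The enumeration oracle certifies the variational bound on any small model:

```r
m <- random_model(3, 2, 2, 2, horizon = 2, seed = 7)
obs <- obs_record(m, run_trial(m, "efe", seed = 7)$observations, t = 2)
b <- infer(m, obs, "efe")
jensen_gap(m, obs, b)    # F - (-ln P(o)), always >= 0
#> [1] 0.1363172
```

## Command line

```sh
inst/cli/aimdp run --model tmaze --scheme both --seed 1 --out out/
inst/cli/aimdp validate --model model.json
inst/cli/aimdp oracle --model random:3,2,2,2,T=2 --seed 7
```

`run` writes per-scheme trial records (`trial.json`, `energies.csv`,
`beliefs.csv`) plus comparison tables of belief rasters and policy
posteriors; `validate` checks a JSON/YAML model config; `oracle` prints a
bound-check report.

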