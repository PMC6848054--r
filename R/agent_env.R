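#' Initialise the generative process (environment)
#'
#' Creates the environment state for a closed-loop trial: samples (or fixes)
#' the true initial hidden state and stores a private RNG state so that
#' trajectories are reproducible regardless of outside RNG use.
#'
#' @param model_true generative process, an [mdp_model()] (may differ from
#'   the agent's model).
#' @param seed integer seed.
#' @param true_initial_state optional fixed initial state index; sampled from
#'   `D` when `NULL`.
#' @return object of class `mdp_env` with fields `state` (true hidden state
#'   index) and a stored RNG state.
#' @export
env_init <- function(model_true, seed = 1L, true_initial_state = NULL) {
  env <- structure(list(model = model_true, state = NA_integer_, rng = NULL),
                   class = "mdp_env")
  env <- with_env_rng(env, function() {
    set.seed(as.integer(seed))
    NULL
  })
  if (is.null(true_initial_state)) {
    env <- with_env_rng(env, function()
      sample.int(model_true$n_states, 1, prob = model_true$D))
    env$state <- env$last
  } else {
    if (!true_initial_state %in% seq_len(model_true$n_states))
      stop_config("true_initial_state out of range")
    env$state <- as.integer(true_initial_state)
  }
  env$last <- NULL
  env
}

# run fn under the environment's private RNG state; store result in env$last
with_env_rng <- function(env, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  if (!is.null(env$rng)) assign(".Random.seed", env$rng, globalenv())
  env$last <- fn()
  env$rng <- get(".Random.seed", globalenv())
  env
}

#' Sample an observation from the current true state
#'
#' Draws one outcome per modality from the likelihood column of the true
#' state.
#'
#' @param env an [env_init()] environment.
#' @return list with updated `env` and `obs`, an integer vector of outcome
#'   indices (one per modality).
#' @export
env_observe <- function(env) {
  model <- env$model
  env <- with_env_rng(env, function()
    vapply(seq_len(model$n_modalities), function(m)
      sample.int(model$n_outcomes[m], 1, prob = model$A[[m]][, env$state]),
      integer(1)))
  obs <- env$last
  env$last <- NULL
  list(env = env, obs = obs)
}

#' Advance the environment by one action
#'
#' Samples the next true hidden state from the action's transition column,
#' then samples one outcome per modality from the likelihood at the new
#' state. Reproducible under the environment's stored RNG state.
#'
#' @param env an [env_init()] environment.
#' @param action action index.
#' @return list with updated `env` (new true state) and `obs`, integer
#'   outcome indices per modality.
#' @export
step_environment <- function(env, action) {
  model <- env$model
  if (!action %in% seq_len(model$n_actions)) stop_config("invalid action")
  env <- with_env_rng(env, function()
    sample.int(model$n_states, 1, prob = model$B[[action]][, env$state]))
  env$state <- env$last
  env$last <- NULL
  env_observe(env)
}

#' Select an action from the policy posterior
#'
#' Marginalises the policy posterior onto actions at time `t` (the action a
#' policy prescribes for the step from `t` to `t + 1`) and either takes the
#' maximum-probability action (`"argmax"`, ties broken by lowest index) or
#' samples from the marginal (`"sample"`).
#'
#' @param pi normalised policy posterior.
#' @param U policy array (`T - 1` x policies) of action indices.
#' @param t time step in `1..T-1`.
#' @param mode `"argmax"` (default) or `"sample"`.
#' @param n_actions number of actions (defaults to `max(U)`).
#' @return action index.
#' @export
select_action <- function(pi, U, t, mode = c("argmax", "sample"),
                          n_actions = max(U)) {
  mode <- match.arg(mode)
  if (t < 1L || t > nrow(U)) stop_config("t out of range for the policy array")
  if (!is_prob_vec(pi, 1e-8)) stop_config("pi must be normalised")
  marg <- vapply(seq_len(n_actions), function(u) sum(pi[U[t, ] == u]),
                 numeric(1))
  if (mode == "argmax") which.max(marg) # which.max takes the lowest tied index
  else sample.int(n_actions, 1, prob = marg)
}

#' Run a closed-loop active-inference trial
#'
#' Simulates one trial: at each time step the agent receives an observation
#' from the environment, updates its beliefs with [infer()] (warm-started
#' from the previous step), and — before the final step — selects and
#' executes an action. Records true states, actions, observations, belief
#' snapshots, per-policy free energies, and a raster of Bayesian-model-
#' averaged state beliefs over (t, tau).
#'
#' @param model the agent's generative model.
#' @param scheme `"efe"` or `"gfe"`.
#' @param seed integer seed for the environment.
#' @param env_model generative process; defaults to the agent's model.
#' @param true_initial_state optional fixed initial state.
#' @param action_mode `"argmax"` or `"sample"` (see [select_action()]).
#' @param tol,max_iters,messages passed to [infer()].
#' @return object of class `mdp_trial` with fields `true_states`, `actions`,
#'   `observations` (modalities x T), `beliefs` (list of `mdp_beliefs` per
#'   t), `raster` (array t x tau x states of BMA beliefs), `energies` (long
#'   data frame), `converged` (per t), `scheme`, `seed`.
#' @export
run_trial <- function(model, scheme = c("efe", "gfe"), seed = 1L,
                      env_model = model, true_initial_state = NULL,
                      action_mode = "argmax", tol = 1e-6, max_iters = 100L,
                      messages = c("marginal", "vmp")) {
  scheme <- match.arg(scheme)
  messages <- match.arg(messages)
  if (env_model$n_actions != model$n_actions ||
      !identical(env_model$n_outcomes, model$n_outcomes))
    stop_structural("agent model and generative process are incompatible")
  Tn <- model$T
  env <- env_init(env_model, seed, true_initial_state)

  true_states <- integer(Tn)
  actions <- integer(max(Tn - 1L, 0L))
  observations <- matrix(NA_integer_, model$n_modalities, Tn)
  beliefs_list <- vector("list", Tn)
  raster <- array(NA_real_, dim = c(Tn, Tn, model$n_states))
  energies <- list()
  converged <- logical(Tn)

  b <- NULL
  ob <- env_observe(env)
  env <- ob$env
  observations[, 1] <- ob$obs

  for (t in seq_len(Tn)) {
    true_states[t] <- env$state
    obs <- obs_record(model, observations[, seq_len(t), drop = FALSE], t = t)
    b <- infer(model, obs, scheme, init = b, tol = tol,
               max_iters = max_iters, messages = messages)
    beliefs_list[[t]] <- b
    converged[t] <- b$converged
    raster[t, , ] <- t(bma_states(b$pi, b$s))
    fe_tab <- data.frame(t = t, policy = seq_len(model$n_policies),
                         F = b$fe$F_p,
                         G = if (scheme == "efe") b$fe$G_p else b$fe$G_future_p,
                         GG = if (scheme == "gfe") b$fe$GG_p else NA_real_,
                         pi = b$pi)
    energies[[t]] <- fe_tab
    if (t < Tn) {
      actions[t] <- select_action(b$pi, model$U, t, mode = action_mode,
                                  n_actions = model$n_actions)
      st <- step_environment(env, actions[t])
      env <- st$env
      observations[, t + 1L] <- st$obs
    }
  }
  structure(list(true_states = true_states, actions = actions,
                 observations = observations, beliefs = beliefs_list,
                 raster = raster, energies = do.call(rbind, energies),
                 converged = converged, scheme = scheme, seed = seed,
                 model = model),
            class = "mdp_trial")
}

#' Simulate trials from a generative model
#'
#' `simulate` method for [mdp_model()] objects: runs `nsim` closed-loop
#' trials (seeds `seed, seed + 1, ...`) and returns a list of
#' [run_trial()] records.
#'
#' @param object an [mdp_model()].
#' @param nsim number of trials.
#' @param seed base seed.
#' @param scheme,... passed to [run_trial()].
#' @return list of `mdp_trial` objects (a single object when `nsim = 1`).
#' @export
simulate.mdp_model <- function(object, nsim = 1, seed = 1L,
                               scheme = "efe", ...) {
  trials <- lapply(seq_len(nsim) - 1L, function(k)
    run_trial(object, scheme = scheme, seed = seed + k, ...))
  if (nsim == 1) trials[[1]] else trials
}

#' @export
print.mdp_trial <- function(x, ...) {
  lab <- x$model$labels
  cat(sprintf("Trial (%s scheme, seed %s): T = %d\n",
              toupper(x$scheme), x$seed, length(x$true_states)))
  st <- if (!is.null(lab$states)) lab$states[x$true_states] else x$true_states
  cat("True states:  ", paste(st, collapse = " -> "), "\n")
  if (length(x$actions)) {
    ac <- if (!is.null(lab$actions)) lab$actions[x$actions] else x$actions
    cat("Actions:      ", paste(ac, collapse = ", "), "\n")
  }
  for (m in seq_len(nrow(x$observations))) {
    om <- x$observations[m, ]
    if (!is.null(lab$outcomes[[m]])) om <- lab$outcomes[[m]][om]
    cat(sprintf("Observations[%d]: %s\n", m, paste(om, collapse = ", ")))
  }
  if (!all(x$converged)) cat("Warning: inference did not converge at t =",
                             which(!x$converged), "\n")
  invisible(x)
}

#' @export
summary.mdp_trial <- function(object, digits = 3, ...) {
  print(object)
  cat("\nFinal policy posterior:\n")
  print(round(object$beliefs[[length(object$beliefs)]]$pi, digits))
  cat("\nBMA state beliefs at final t (states x tau):\n")
  print(round(t(object$raster[dim(object$raster)[1], , ]), digits))
  invisible(object)
}

#' Raster plot of belief trajectories
#'
#' Plots the Bayesian-model-averaged posterior beliefs about hidden states as
#' one raster per observation time `t`: rows are states (darker = more
#' probable), columns are the represented times `tau` from the start to the
#' end of the planning horizon.
#'
#' @param x an `mdp_trial`.
#' @param state_labels optional state names for the axis.
#' @param ... passed to [graphics::image()].
#' @export
plot.mdp_trial <- function(x, state_labels = x$model$labels$states, ...) {
  Tn <- dim(x$raster)[1]
  n_s <- dim(x$raster)[3]
  op <- graphics::par(mfrow = c(1, Tn), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (t in seq_len(Tn)) {
    z <- x$raster[t, , ] # tau x states
    graphics::image(x = seq_len(Tn), y = seq_len(n_s), z = z,
                    zlim = c(0, 1), col = grey.colors(64, 0.95, 0.05),
                    xlab = "tau", ylab = if (t == 1) "state" else "",
                    main = sprintf("t = %d", t), axes = FALSE, ...)
    graphics::axis(1, at = seq_len(Tn))
    if (t == 1 && !is.null(state_labels))
      graphics::axis(2, at = seq_len(n_s), labels = state_labels, las = 2,
                     cex.axis = 0.6)
    else graphics::axis(2, at = seq_len(n_s))
    graphics::box()
  }
  invisible(x)
}
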