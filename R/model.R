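#' Construct a discrete-state generative model
#'
#' Bundles the categorical sufficient statistics of a partially observed
#' Markov decision process: per-modality likelihood arrays, action-conditioned
#' transition arrays, log-preferences over outcomes, priors over initial
#' states and policies, and the policy set.
#'
#' @param A likelihood: a column-stochastic matrix (outcomes x states), or a
#'   list of such matrices, one per outcome modality. Column `j` holds
#'   `P(o = i | s = j)`.
#' @param B transitions: a column-stochastic matrix (states x states) or a
#'   list of such matrices, one per action. Column `j` holds
#'   `P(s' = i | s = j, u)`.
#' @param C outcome log-preferences: per modality, either a vector over
#'   outcomes (recycled across time) or an outcomes x `T` matrix. Each time
#'   column is softmax-normalised so that `exp(C)` is a distribution over
#'   outcomes, i.e. a prior `P(o_tau)`.
#' @param D prior over the initial hidden state.
#' @param E prior over policies; defaults to uniform.
#' @param U policy array with `T - 1` rows and one column per policy; entry
#'   `(tau, k)` is the action index taken at step `tau` under policy `k`.
#' @param horizon planning horizon `T` (number of time steps); defaults to
#'   `nrow(U) + 1`.
#' @param labels optional list of character vectors (`states`, `actions`,
#'   `outcomes` — a list per modality) used for printing.
#' @param check validate stochasticity on construction (default `TRUE`).
#' @return an object of class `mdp_model`.
#' @seealso [validate_model()], [build_tmaze()], [random_model()]
#' @export
mdp_model <- function(A, B, C, D, E = NULL, U, horizon = NULL,
                      labels = NULL, check = TRUE) {
  if (is.matrix(A)) A <- list(A)
  if (is.matrix(B)) B <- list(B)
  A <- lapply(A, as.matrix)
  B <- lapply(B, as.matrix)
  U <- as.matrix(U)
  storage.mode(U) <- "integer"
  if (is.null(horizon)) horizon <- nrow(U) + 1L
  horizon <- as.integer(horizon)

  n_states <- length(D)
  n_actions <- length(B)
  n_policies <- ncol(U)
  if (is.null(E)) E <- rep(1 / n_policies, n_policies)

  # structural checks (distinct from stochasticity violations)
  for (m in seq_along(A)) {
    if (ncol(A[[m]]) != n_states)
      stop_structural(sprintf("A[[%d]] has %d columns but D implies %d states",
                              m, ncol(A[[m]]), n_states))
  }
  for (u in seq_along(B)) {
    if (!all(dim(B[[u]]) == c(n_states, n_states)))
      stop_structural(sprintf("B[[%d]] must be %d x %d", u, n_states, n_states))
  }
  if (length(E) != n_policies)
    stop_structural("length(E) must equal the number of policies (columns of U)")
  if (nrow(U) != horizon - 1L)
    stop_structural(sprintf("U must have T - 1 = %d rows, got %d",
                            horizon - 1L, nrow(U)))
  if (any(is.na(U)) || any(U < 1L) || any(U > n_actions))
    stop_structural("U references actions outside 1..n_actions")

  # normalise C storage: per-modality (outcomes x T) log-probability matrices
  if (!is.list(C)) C <- list(C)
  if (length(C) != length(A))
    stop_structural("C must have one element per outcome modality")
  C <- lapply(seq_along(C), function(m) {
    cm <- C[[m]]
    if (is.vector(cm)) cm <- matrix(cm, nrow = length(cm), ncol = horizon)
    cm <- as.matrix(cm)
    if (nrow(cm) != nrow(A[[m]]))
      stop_structural(sprintf("C[[%d]] has %d outcomes but A[[%d]] has %d",
                              m, nrow(cm), m, nrow(A[[m]])))
    if (ncol(cm) != horizon)
      stop_structural(sprintf("C[[%d]] must have T = %d time columns", m, horizon))
    apply(cm, 2, lsoftmax)
  })

  model <- structure(list(
    A = A, B = B, C = C, D = as.numeric(D), E = as.numeric(E), U = U,
    T = horizon,
    n_states = n_states, n_actions = n_actions, n_policies = n_policies,
    n_modalities = length(A),
    n_outcomes = vapply(A, nrow, integer(1)),
    labels = labels
  ), class = "mdp_model")

  if (check) {
    rep <- validate_model(model)
    if (!rep$ok)
      stop_config(paste0("model fails validation:\n",
                         paste(utils::capture.output(print(rep)), collapse = "\n")))
  }
  model
}

#' Validate the stochastic structure of a generative model
#'
#' Checks that every column of every likelihood and transition array is a
#' probability distribution, that the state and policy priors normalise, that
#' exponentiated preferences normalise per time step, and that the policy
#' array indexes valid actions. Dimension mismatches raise a structural error
#' at construction; this function reports normalisation/negativity violations
#' without mutating the model.
#'
#' @param model an [mdp_model()].
#' @param tol numeric tolerance on column sums (default `1e-10`).
#' @return an object of class `mdp_validation` with fields `ok` (logical) and
#'   `violations` (data frame with columns `field`, `index`, `description`).
#' @export
validate_model <- function(model, tol = 1e-10) {
  v <- list()
  add <- function(field, index, description) {
    v[[length(v) + 1L]] <<- data.frame(field = field, index = index,
                                       description = description,
                                       stringsAsFactors = FALSE)
  }
  check_cols <- function(mat, field) {
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      if (any(col < -tol))
        add(field, sprintf("column %d", j),
            sprintf("negative entry (min %.3g)", min(col)))
      if (abs(sum(col) - 1) > tol)
        add(field, sprintf("column %d", j),
            sprintf("column sums to %.10g, not 1", sum(col)))
    }
  }
  for (m in seq_along(model$A)) check_cols(model$A[[m]], sprintf("A[[%d]]", m))
  for (u in seq_along(model$B)) check_cols(model$B[[u]], sprintf("B[[%d]]", u))
  if (any(model$D < -tol) || abs(sum(model$D) - 1) > tol)
    add("D", "", sprintf("not a distribution (sum %.10g)", sum(model$D)))
  if (any(model$E < -tol) || abs(sum(model$E) - 1) > tol)
    add("E", "", sprintf("not a distribution (sum %.10g)", sum(model$E)))
  for (m in seq_along(model$C)) {
    p <- exp(model$C[[m]])
    for (j in seq_len(ncol(p)))
      if (abs(sum(p[, j]) - 1) > 1e-8)
        add(sprintf("C[[%d]]", m), sprintf("time %d", j),
            "exp(C) column does not normalise")
  }
  if (any(model$U < 1L) || any(model$U > model$n_actions))
    add("U", "", "action index out of range")

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), index = character(),
               description = character(), stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "mdp_validation")
}

#' @export
print.mdp_validation <- function(x, ...) {
  if (x$ok) {
    cat("Model valid: all arrays column-stochastic, priors normalised.\n")
  } else {
    cat(sprintf("Model INVALID: %d violation(s)\n", nrow(x$violations)))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Negative entropy of a likelihood mapping, per hidden state
#'
#' For a column-stochastic likelihood matrix returns the vector `H` with
#' `H_i = sum_j A_ji * ln A_ji`: the negative Shannon entropy of the outcome
#' distribution conditioned on state `i`. Entries are `<= 0`; they vanish for
#' deterministic (one-hot) columns. The expected likelihood entropy
#' `-s . H` under state beliefs `s` is the ambiguity term of the expected
#' free energy.
#'
#' @param A likelihood matrix (outcomes x states), column-stochastic.
#' @return numeric vector of length `ncol(A)`, all entries `<= 0`.
#' @export
likelihood_neg_entropy <- function(A) {
  A <- as.matrix(A)
  colSums(A * ln(A))
}

# per-modality negative entropies summed into one per-state vector
neg_entropy_sum <- function(model) {
  Reduce(`+`, lapply(model$A, likelihood_neg_entropy))
}

#' Enumerate policies as action sequences
#'
#' Generates all distinct action sequences of a given depth, merging
#' sequences made equivalent by absorbing states and optionally appending a
#' forced tail that repeats the final action. Action indices are interpreted
#' as "go to location u" moves, so an action in the `absorbing` set commits
#' the agent to that state: subsequent free choices are irrelevant and the
#' remainder of the sequence is replaced by the absorbing action before
#' de-duplication.
#'
#' @param n_actions number of available actions.
#' @param depth number of free action choices (`>= 1`).
#' @param absorbing integer set of absorbing go-to actions (may be empty).
#' @param tail_steps number of forced trailing steps repeating the last
#'   action ("stay where you are" under go-to semantics).
#' @return an integer matrix with `depth + tail_steps` rows, one column per
#'   distinct policy, in lexicographic order.
#' @export
enumerate_policies <- function(n_actions, depth, absorbing = integer(0),
                               tail_steps = 0L) {
  if (n_actions < 1L) stop_config("empty action set")
  if (depth < 1L) stop_config("depth must be >= 1")
  grids <- rev(expand.grid(rev(replicate(depth, seq_len(n_actions),
                                         simplify = FALSE))))
  seqs <- t(as.matrix(grids)) # depth x n_actions^depth, lexicographic columns
  if (length(absorbing)) {
    for (k in seq_len(ncol(seqs))) {
      hit <- which(seqs[, k] %in% absorbing)
      if (length(hit) && hit[1] < depth)
        seqs[(hit[1] + 1):depth, k] <- seqs[hit[1], k]
    }
  }
  seqs <- seqs[, !duplicated(t(seqs)), drop = FALSE]
  if (tail_steps > 0L) {
    tail <- matrix(rep(seqs[depth, ], each = tail_steps), nrow = tail_steps)
    seqs <- rbind(seqs, tail)
  }
  storage.mode(seqs) <- "integer"
  dimnames(seqs) <- NULL
  seqs
}

#' Random small generative model
#'
#' Samples a reproducible random model with column-stochastic arrays (flat
#' Dirichlet columns), Gaussian preference logits, and a random policy array.
#' Intended for property tests and for exercising the enumeration oracle.
#'
#' @param n_states,n_actions,n_policies,horizon model dimensions.
#' @param n_outcomes integer vector, outcomes per modality.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return an [mdp_model()] that passes [validate_model()].
#' @export
random_model <- function(n_states = 3, n_outcomes = 2, n_actions = 2,
                         n_policies = 2, horizon = 2, seed = 1) {
  stopifnot(n_states >= 1, all(n_outcomes >= 1), n_actions >= 1,
            n_policies >= 1, horizon >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  rdirich_cols <- function(nr, nc) {
    m <- matrix(stats::rgamma(nr * nc, shape = 1), nr, nc)
    sweep(m, 2, colSums(m), "/")
  }
  A <- lapply(n_outcomes, function(no) rdirich_cols(no, n_states))
  B <- replicate(n_actions, rdirich_cols(n_states, n_states), simplify = FALSE)
  C <- lapply(n_outcomes, function(no)
    matrix(stats::rnorm(no * horizon), no, horizon))
  D <- as.numeric(rdirich_cols(n_states, 1))
  E <- as.numeric(rdirich_cols(n_policies, 1))
  U <- if (horizon > 1)
    matrix(sample.int(n_actions, (horizon - 1) * n_policies, replace = TRUE),
           horizon - 1, n_policies)
  else matrix(integer(0), 0, n_policies)
  mdp_model(A, B, C, D, E, U, horizon = horizon)
}

#' @export
print.mdp_model <- function(x, ...) {
  cat(sprintf(
    "Generative model: %d states, %d action(s), %d polic%s, horizon T = %d\n",
    x$n_states, x$n_actions, x$n_policies,
    if (x$n_policies == 1) "y" else "ies", x$T))
  cat(sprintf("Outcome modalities: %s\n",
              paste(sprintf("%d outcomes", x$n_outcomes), collapse = ", ")))
  if (!is.null(x$labels$states))
    cat("States:", paste(x$labels$states, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mdp_model <- function(object, ...) {
  print(object)
  H <- neg_entropy_sum(object)
  cat("Per-state likelihood negative entropy (summed over modalities):\n")
  print(round(H, 4))
  print(validate_model(object))
  invisible(object)
}
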