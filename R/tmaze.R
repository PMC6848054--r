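#' Build the T-maze epistemic-foraging model
#'
#' Constructs the classic four-location T-maze task as a generative model
#' with a single joint hidden-state factor of 8 states (4 locations x 2
#' contexts). Location 1 is the start arm, locations 2 and 3 are the baited
#' arms (absorbing: once entered, the agent cannot leave), and location 4
#' holds the instructional cue. In context 1 the unconditioned stimulus (US,
#' reward) is in the left arm with probability `p_us`; in context 2 it is in
#' the right arm. The cue modality emits a conditioned stimulus (CS) that is
#' ambiguous (50/50 blue/green) at location 1 but deterministic on context at
#' location 4 (context 1 -> blue, context 2 -> green), so visiting the cue
#' location resolves context uncertainty. The location modality is an
#' identity mapping on the location factor.
#'
#' The agent starts at location 1 with a uniform prior over contexts, has
#' four "go to location u" actions, a uniform prior over the 10 distinct
#' policies (two free moves, forced stay thereafter), and a planning horizon
#' of `horizon` steps.
#'
#' @param p_us probability of the US in the context-correct arm (default
#'   0.9); the incorrect arm emits the US with probability `1 - p_us`
#'   (symmetric completion).
#' @param preference_logits named numeric vector `c(US=, CS=, NS=)` of cue
#'   log-preferences; must be ordered `US > CS > NS`. Both CS colours share
#'   the CS value. Location preferences are flat.
#' @param left_arm which location (2 or 3) is the left arm, i.e. the arm
#'   baited in context 1.
#' @param horizon planning horizon (default 4: three actions, the third a
#'   forced stay).
#' @return an [mdp_model()] with two outcome modalities (`location`, `cue`).
#' @export
build_tmaze <- function(p_us = 0.9,
                        preference_logits = c(US = 1.5, CS = 1, NS = -3),
                        left_arm = 2, horizon = 4) {
  if (!(p_us > 0 && p_us <= 1)) stop_config("p_us must be in (0, 1]")
  pl <- preference_logits
  if (!all(c("US", "CS", "NS") %in% names(pl)))
    stop_config("preference_logits must name US, CS and NS")
  if (!(pl["US"] > pl["CS"] && pl["CS"] > pl["NS"]))
    stop_config("preferences must be ordered US > CS > NS")
  if (!left_arm %in% c(2L, 3L)) stop_config("left_arm must be 2 or 3")
  right_arm <- if (left_arm == 2L) 3L else 2L

  n_loc <- 4L
  n_ctx <- 2L
  n_s <- n_loc * n_ctx
  idx <- function(loc, ctx) loc + n_loc * (ctx - 1L) # location-major

  # modality 1: location (identity on the location factor)
  A_loc <- matrix(0, n_loc, n_s)
  for (ctx in 1:n_ctx) for (loc in 1:n_loc) A_loc[loc, idx(loc, ctx)] <- 1

  # modality 2: cue -- outcomes CS-blue, CS-green, US, NS
  CUE <- c(blue = 1L, green = 2L, us = 3L, ns = 4L)
  A_cue <- matrix(0, 4, n_s)
  for (ctx in 1:n_ctx) {
    A_cue[CUE["blue"], idx(1, ctx)] <- 0.5
    A_cue[CUE["green"], idx(1, ctx)] <- 0.5
    A_cue[if (ctx == 1) CUE["blue"] else CUE["green"], idx(4, ctx)] <- 1
    correct <- if (ctx == 1) left_arm else right_arm
    wrong <- if (ctx == 1) right_arm else left_arm
    A_cue[CUE["us"], idx(correct, ctx)] <- p_us
    A_cue[CUE["ns"], idx(correct, ctx)] <- 1 - p_us
    A_cue[CUE["us"], idx(wrong, ctx)] <- 1 - p_us
    A_cue[CUE["ns"], idx(wrong, ctx)] <- p_us
  }

  # actions: go to location u; 2 and 3 are absorbing; context never changes
  B <- lapply(1:n_loc, function(u) {
    Bu <- matrix(0, n_s, n_s)
    for (ctx in 1:n_ctx) for (loc in 1:n_loc) {
      dest <- if (loc %in% c(2L, 3L)) loc else u
      Bu[idx(dest, ctx), idx(loc, ctx)] <- 1
    }
    Bu
  })

  C_loc <- rep(0, n_loc)
  C_cue <- c(pl["CS"], pl["CS"], pl["US"], pl["NS"])

  D <- numeric(n_s)
  D[idx(1, 1)] <- 0.5
  D[idx(1, 2)] <- 0.5

  U <- enumerate_policies(n_loc, depth = 2L, absorbing = c(2L, 3L),
                          tail_steps = horizon - 3L)

  labels <- list(
    states = as.vector(outer(paste0("loc", 1:n_loc),
                             paste0("ctx", 1:n_ctx), paste, sep = "/")),
    actions = paste0("goto", 1:n_loc),
    outcomes = list(location = paste0("loc", 1:n_loc),
                    cue = c("CS-blue", "CS-green", "US", "NS"))
  )

  model <- mdp_model(A = list(A_loc, A_cue), B = B,
                     C = list(C_loc, as.numeric(C_cue)),
                     D = D, U = U, horizon = horizon, labels = labels)
  model$tmaze <- list(left_arm = left_arm, right_arm = right_arm,
                      p_us = p_us, n_loc = n_loc, idx = NULL)
  model
}

# marginalise a T-maze joint-state belief onto the location factor
tmaze_location_marginal <- function(s) {
  n_loc <- 4L
  s[1:n_loc] + s[n_loc + (1:n_loc)]
}
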