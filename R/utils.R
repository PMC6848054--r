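#' @keywords internal
#' @importFrom stats simulate setNames
#' @importFrom grDevices grey.colors
"_PACKAGE"

# Log-floor convention: deterministic and absorbing structures contain exact
# zeros, so every logarithm in the belief-update algebra is ln(max(x, exp(-16))).
LOG_FLOOR <- exp(-16)

ln <- function(x) log(pmax(x, LOG_FLOOR))

#' Numerically stable softmax
#'
#' Normalised exponential with max-subtraction.
#'
#' @param x numeric vector of logits; `-Inf` entries receive zero mass.
#' @return probability vector summing to 1.
#' @export
softmax <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(rep(1 / length(x), length(x)))
  y <- exp(x - m)
  y / sum(y)
}

# log-softmax (normalised log-probabilities), max-shifted; -Inf preserved
lsoftmax <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(rep(-log(length(x)), length(x)))
  x <- x - m
  x - log(sum(exp(x)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# renormalise a non-negative vector; guards against all-zero input
norm1 <- function(x) {
  s <- sum(x)
  if (s <= 0) rep(1 / length(x), length(x)) else x / s
}

one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

is_prob_vec <- function(x, tol = 1e-10) {
  all(x >= -tol) && abs(sum(x) - 1) <= tol
}

# KL divergence between categorical distributions (log-floored)
kl_cat <- function(p, q) sum(p * (ln(p) - ln(q)))

stop_structural <- function(msg) {
  stop(structure(class = c("aimdp_structure_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_config <- function(msg) {
  stop(structure(class = c("aimdp_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
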