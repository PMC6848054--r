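#' Read a generative model from a config file
#'
#' Loads a JSON (or YAML, when the `yaml` package is available) model
#' specification with keys `A` (list per modality of outcomes x states
#' arrays), `B` (list per action of states x states arrays), `C` (list per
#' modality of log-preference vectors or outcomes x T arrays), `D`, `E`
#' (optional), `U` (T-1 x policies action indices) and `T`. Arrays are
#' written row by row. The file is schema-checked and the resulting model
#' validated; malformed files are rejected.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return an [mdp_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    # keep nested lists: simplification would merge equal-sized matrices
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else stop_config("model config must be .json, .yaml or .yml")

  need <- c("A", "B", "C", "D", "U", "T")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_config(paste("model config missing keys:", paste(miss, collapse = ", ")))

  # arrays are stored row by row; scalars/vectors may arrive as lists
  as_num <- function(x) as.numeric(unlist(x))
  as_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as_num))
  }
  is_mat_like <- function(x) is.matrix(x) ||
    (is.list(x) && length(x) > 0 && (is.list(x[[1]]) || length(x[[1]]) > 1))
  as_mat_list <- function(x) {
    if (is_mat_like(x) && !is.list(x[[1]])) list(as_mat(x))
    else if (is.list(x) && all(vapply(x, is_mat_like, logical(1))))
      lapply(x, as_mat)
    else list(as_mat(x))
  }
  C_list <- if (is.list(raw$C) && all(vapply(raw$C, is_mat_like, logical(1))))
    lapply(raw$C, as_mat)
  else if (is.list(raw$C) && is.list(raw$C[[1]])) lapply(raw$C, as_num)
  else list(as_num(raw$C))

  mdp_model(A = as_mat_list(raw$A), B = as_mat_list(raw$B), C = C_list,
            D = as_num(raw$D),
            E = if (!is.null(raw$E)) as_num(raw$E),
            U = as_mat(raw$U), horizon = as.integer(unlist(raw$T)))
}

#' Write a generative model to a config file
#'
#' @param model an [mdp_model()].
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  spec <- list(A = model$A, B = model$B, C = model$C, D = model$D,
               E = model$E, U = model$U, T = model$T)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(spec, path, digits = NA, matrix = "rowmajor",
                         auto_unbox = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("the yaml package is required for YAML configs")
    to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    spec$A <- lapply(spec$A, to_rows)
    spec$B <- lapply(spec$B, to_rows)
    spec$C <- lapply(spec$C, to_rows)
    spec$U <- to_rows(spec$U)
    yaml::write_yaml(spec, path, precision = 15L)
  } else stop_config("model config must be .json, .yaml or .yml")
  invisible(path)
}

#' Serialise a trial record to a directory
#'
#' Writes `trial.json` (metadata, true states, actions, observations,
#' convergence flags), `energies.csv` (per-time per-policy free energies and
#' policy posterior) and `beliefs.csv` (the BMA belief raster in long format:
#' `t`, `tau`, `state`, `probability`).
#'
#' @param trial an `mdp_trial` from [run_trial()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(scheme = trial$scheme, seed = trial$seed,
               T = length(trial$true_states),
               true_states = trial$true_states, actions = trial$actions,
               observations = trial$observations,
               converged = trial$converged)
  jsonlite::write_json(meta, file.path(dir, "trial.json"),
                       digits = NA, matrix = "rowmajor", auto_unbox = TRUE,
                       pretty = TRUE)
  utils::write.csv(trial$energies, file.path(dir, "energies.csv"),
                   row.names = FALSE)
  utils::write.csv(raster_long(trial), file.path(dir, "beliefs.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# BMA raster as a long data frame (t, tau, state, probability)
raster_long <- function(trial) {
  d <- dim(trial$raster)
  g <- expand.grid(t = seq_len(d[1]), tau = seq_len(d[2]), state = seq_len(d[3]))
  g$probability <- as.numeric(trial$raster)
  g
}
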