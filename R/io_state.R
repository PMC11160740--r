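# Run-state persistence: everything needed to resume a training
# trajectory bit-for-bit (field parameters, optimizer moments, latents,
# poses, configuration, RNG state).

.STATE_VERSION <- 1L

#' Save a training state to a run directory
#'
#' @param state a `train_state` (or the partial state used mid-run).
#' @param run_dir directory (created if missing).
#' @return `run_dir`, invisibly.
#' @export
save_state <- function(state, run_dir) {
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  payload <- list(version = .STATE_VERSION, state = unclass(state),
                  rng = rng)
  saveRDS(payload, file.path(run_dir, "state.rds"))
  cfg <- state$config
  if (!is.null(cfg)) {
    yaml::write_yaml(cfg[!vapply(cfg, is.function, logical(1))],
                     file.path(run_dir, "config.yaml"))
  }
  invisible(run_dir)
}

#' Load a training state
#'
#' Restores the saved state including the RNG stream, so that continuing
#' training reproduces an uninterrupted run exactly.
#'
#' @param run_dir directory written by [save_state()].
#' @return the `train_state`.
#' @export
load_state <- function(run_dir) {
  f <- file.path(run_dir, "state.rds")
  if (!file.exists(f)) stop("no saved state in ", run_dir)
  payload <- readRDS(f)
  if (is.null(payload$version) || payload$version != .STATE_VERSION)
    stop("saved state version ", payload$version,
         " does not match supported version ", .STATE_VERSION)
  if (!is.null(payload$rng))
    assign(".Random.seed", payload$rng, envir = globalenv())
  state <- payload$state
  class(state) <- "train_state"
  state
}

#' Read a key-value run configuration file
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
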