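# Plain-text input/output: trajectory and order-series CSV, drift/diffusion
# CSV, fixed-point JSON, and reproducibility metadata sidecars.

.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

.write_csv_fmt <- function(df, file) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Write an order-parameter series as CSV
#'
#' Columns `t`, `phi`, `n_moving` (empty when unknown); floats carry 12
#' significant digits. Samples flagged undefined are written with
#' `n_moving = 0`.
#'
#' @param series an [order_series()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_order_series <- function(series, file) {
  df <- data.frame(t = series$t, phi = series$phi, n_moving = series$n_moving)
  .write_csv_fmt(df, file)
  invisible(file)
}

#' Read an order-parameter series from CSV
#'
#' Expects the [write_order_series()] layout (`t`, `phi`, optional
#' `n_moving`). Samples with `n_moving == 0` are flagged undefined. Also the
#' entry point for externally supplied (e.g. experimental) order series.
#'
#' @param file path to a CSV file.
#' @return an [order_series()].
#' @export
read_order_series <- function(file) {
  df <- read.csv(file)
  if (!all(c("t", "phi") %in% names(df)))
    stop("order-series CSV needs columns t and phi")
  nm <- if ("n_moving" %in% names(df)) df$n_moving else NULL
  undef <- if (!is.null(nm)) !is.na(nm) & nm == 0 else NULL
  order_series(df$t, df$phi, n_moving = nm, undefined = undef)
}

#' Write a trajectory in long CSV format
#'
#' One row per (sample time, particle): columns `t`, `particle`, `x`, `u`,
#' `moving`. Requires a trajectory run with `store_states = TRUE`.
#'
#' @param traj a `swarm_trajectory`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  if (is.null(traj$states))
    stop("trajectory was run without store_states = TRUE")
  st <- traj$states
  if (is.null(st$x) || is.null(st$u))
    stop("long-format export is defined for the 1D models")
  ns <- nrow(st$x); N <- ncol(st$x)
  df <- data.frame(t = rep(traj$series$t, times = N),
                   particle = rep(seq_len(N), each = ns),
                   x = as.vector(st$x), u = as.vector(st$u),
                   moving = as.vector(st$moving))
  df <- df[order(df$t, df$particle), ]
  .write_csv_fmt(df, file)
  invisible(file)
}

#' Write a drift/diffusion estimate as CSV
#'
#' @param est an [estimate_FD()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fd_estimate <- function(est, file) {
  .write_csv_fmt(as.data.frame(est), file)
  invisible(file)
}

#' Write classified fixed points as JSON
#'
#' @param fp a data frame from [classify_fixed_points()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fixed_points <- function(fp, file) {
  jsonlite::write_json(fp, file, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Write a reproducibility metadata sidecar
#'
#' JSON record of everything needed to re-run a simulation bit-exactly:
#' model identifier, full parameter set (with its class), seed, step count,
#' sampling stride, and the package version.
#'
#' @param traj a `swarm_trajectory`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_run_metadata <- function(traj, file) {
  meta <- list(model = traj$model,
               param_class = class(traj$params),
               params = unclass(traj$params),
               seed = traj$seed,
               n_steps = traj$n_steps,
               sample_every = traj$sample_every,
               package = "locustmarch",
               version = as.character(packageVersion("locustmarch")))
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(meta, file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' Re-run a simulation from its metadata sidecar
#'
#' Reconstructs the parameter object and repeats the run; with an unchanged
#' package version the result matches the original bit-exactly.
#'
#' @param file path to a sidecar written by [write_run_metadata()].
#' @param store_states also store state snapshots?
#' @return a `swarm_trajectory`.
#' @export
run_from_metadata <- function(file, store_states = FALSE) {
  meta <- jsonlite::read_json(file, simplifyVector = TRUE)
  params <- meta$params
  if ("N" %in% names(params)) params$N <- as.integer(params$N)
  if ("n_c_moving" %in% names(params))
    params$n_c_moving <- as.integer(params$n_c_moving)
  class(params) <- meta$param_class
  run_simulation(meta$model, params, n_steps = meta$n_steps,
                 sample_every = meta$sample_every, seed = meta$seed,
                 store_states = store_states)
}
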