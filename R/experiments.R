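# Reproducible comparative experiments: density scans, system-size scans and
# model comparisons under matched seeds.

# Mean order and switching statistics of one series after burn-in.
.series_stats <- function(series, p = 0.7, burn_in_frac = 0.1) {
  span <- series$t[nrow(series)] - series$t[1]
  s <- trim_series(series, burn_in = burn_in_frac * span)
  tr <- transitions(s, p = p)
  list(mean_order = mean(abs(s$phi[!s$undefined])),
       rate = tr$rate, n_switches = tr$n_switches,
       total_time = tr$total_time)
}

.with_rho <- function(params, rho) {
  params$rho <- rho
  params$L <- params$N / rho
  params
}

.with_N <- function(params, N, fixed = c("L", "rho")) {
  fixed <- match.arg(fixed)
  params$N <- as.integer(N)
  if (fixed == "L") params$rho <- N / params$L else params$L <- N / params$rho
  params
}

#' Density scan of mean order and switching rate
#'
#' Sweeps the linear density `rho` at fixed `N` (the ring length is adjusted
#' to `N / rho`), running each grid point for every seed and reporting the
#' mean order parameter and the metastable switching rate per run.
#' Deterministic given the seeds.
#'
#' @param model model identifier (see [run_simulation()]).
#' @param params base parameter object; its `N` is kept fixed.
#' @param rho_grid densities to sweep.
#' @param seeds integer seeds (one run per seed per grid point).
#' @param n_steps steps per run.
#' @param sample_every sampling stride.
#' @param p order cutoff for [transitions()].
#' @param burn_in_frac fraction of each run discarded before statistics.
#' @param moving_only analyse the moving-only order parameter?
#' @return a data frame of class `scan_result` with columns `model`, `rho`,
#'   `N`, `L`, `seed`, `mean_order`, `rate`, `n_switches`, `total_time`.
#' @export
scan_density <- function(model, params, rho_grid, seeds, n_steps,
                         sample_every = 1, p = 0.7, burn_in_frac = 0.1,
                         moving_only = FALSE) {
  if (length(rho_grid) == 0) stop("rho_grid must be non-empty")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  rows <- list()
  for (rho in rho_grid) {
    pr <- .with_rho(params, rho)
    for (s in seeds) {
      traj <- run_simulation(model, pr, n_steps = n_steps,
                             sample_every = sample_every, seed = s)
      st <- .series_stats(order_parameter(traj, moving_only = moving_only),
                          p = p, burn_in_frac = burn_in_frac)
      rows[[length(rows) + 1]] <-
        data.frame(model = model, rho = rho, N = pr$N, L = pr$L, seed = s,
                   mean_order = st$mean_order, rate = st$rate,
                   n_switches = st$n_switches, total_time = st$total_time)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' System-size scan of switching rates
#'
#' Sweeps the number of particles `N`, holding either the ring length `L`
#' fixed (the small-arena setting, where switching rates fall steeply with
#' `N`) or the density `rho` fixed (the thermodynamic-limit setting).
#'
#' @param model,params,seeds,n_steps,sample_every,p,burn_in_frac,moving_only
#'   as in [scan_density()].
#' @param N_grid particle numbers to sweep.
#' @param fixed `"L"` or `"rho"`.
#' @return a `scan_result` data frame (same schema as [scan_density()]).
#' @export
scan_N <- function(model, params, N_grid, seeds, n_steps, fixed = c("L", "rho"),
                   sample_every = 1, p = 0.7, burn_in_frac = 0.1,
                   moving_only = FALSE) {
  fixed <- match.arg(fixed)
  if (length(N_grid) == 0) stop("N_grid must be non-empty")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  rows <- list()
  for (N in N_grid) {
    pr <- .with_N(params, N, fixed)
    for (s in seeds) {
      traj <- run_simulation(model, pr, n_steps = n_steps,
                             sample_every = sample_every, seed = s)
      st <- .series_stats(order_parameter(traj, moving_only = moving_only),
                          p = p, burn_in_frac = burn_in_frac)
      rows[[length(rows) + 1]] <-
        data.frame(model = model, rho = pr$rho, N = pr$N, L = pr$L, seed = s,
                   mean_order = st$mean_order, rate = st$rate,
                   n_switches = st$n_switches, total_time = st$total_time)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Seed-averaged summary of a scan
#'
#' @param scan a `scan_result` from [scan_density()] or [scan_N()].
#' @param by grouping column, `"rho"` or `"N"`.
#' @return a data frame with per-group means and standard errors of the mean
#'   order and switching rate.
#' @export
summarize_scan <- function(scan, by = c("rho", "N")) {
  by <- match.arg(by)
  g <- split(scan, scan[[by]])
  out <- do.call(rbind, lapply(g, function(d) {
    data.frame(value = d[[by]][1], n_runs = nrow(d),
               mean_order = mean(d$mean_order),
               se_order = sd(d$mean_order) / sqrt(nrow(d)),
               rate = mean(d$rate),
               se_rate = sd(d$rate) / sqrt(nrow(d)))
  }))
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}

#' Compare models under identical seeds and geometry
#'
#' Runs each model with the same parameter record and the same seeds (so
#' the models are coupled on common random numbers) and reports per-run mean
#' order and switching rate; optionally also an ensemble drift/diffusion
#' profile per model via [fd_ensemble()].
#'
#' @param models character vector of at least 2 model identifiers.
#' @param params shared parameter object (must be valid for every model).
#' @param seeds integer seeds shared across models.
#' @param n_steps steps per run.
#' @param sample_every sampling stride.
#' @param p order cutoff.
#' @param burn_in_frac burn-in fraction.
#' @param fd_args optional list of arguments for [fd_ensemble()] (`dt_cg`,
#'   `phi0_grid`, `replicates`, `seed`, ...); `NULL` skips profiles.
#' @return a list with `summary` (data frame: `model`, `seed`,
#'   `mean_order`, `rate`, `n_switches`) and `fd` (named list of
#'   `fd_estimate`s or `NULL`).
#' @export
compare_models <- function(models, params, seeds, n_steps, sample_every = 1,
                           p = 0.7, burn_in_frac = 0.1, fd_args = NULL) {
  if (length(models) < 2) stop("give at least 2 models to compare")
  rows <- list()
  for (model in models) {
    mo <- model == "pause_and_go"
    for (s in seeds) {
      traj <- run_simulation(model, params, n_steps = n_steps,
                             sample_every = sample_every, seed = s)
      st <- .series_stats(order_parameter(traj, moving_only = mo),
                          p = p, burn_in_frac = burn_in_frac)
      rows[[length(rows) + 1]] <-
        data.frame(model = model, seed = s, mean_order = st$mean_order,
                   rate = st$rate, n_switches = st$n_switches)
    }
  }
  fd <- NULL
  if (!is.null(fd_args)) {
    fd <- lapply(models, function(model) {
      do.call(fd_ensemble, c(list(model = model, params = params,
                                  moving_only = model == "pause_and_go"),
                             fd_args))
    })
    names(fd) <- models
  }
  list(summary = do.call(rbind, rows), fd = fd)
}
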