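# Order-parameter extraction, metastable-state switching statistics, and
# binned estimation of the effective drift/diffusion functions.

#' Order-parameter time series
#'
#' A sampled series of the directional order parameter `phi(t)`, with the
#' number of moving particles and an `undefined` mask for samples where the
#' moving-only order has no support (no movers). The sampling interval is
#' stored as attribute `dt_sample`.
#'
#' @param t increasing, uniformly spaced sample times.
#' @param phi order values.
#' @param n_moving moving-particle counts (optional).
#' @param undefined logical mask of samples to skip (optional).
#' @return an object of class `c("order_series", "data.frame")`.
#' @export
order_series <- function(t, phi, n_moving = NULL, undefined = NULL) {
  n <- length(t)
  if (length(phi) != n) stop("t and phi must have equal length")
  if (n >= 2) {
    dts <- diff(t)
    if (any(dts <= 0)) stop("t must be strictly increasing")
    if (max(dts) - min(dts) > 1e-8 * max(dts))
      stop("t must be uniformly spaced")
    dt_sample <- dts[1]
  } else dt_sample <- NA_real_
  if (is.null(n_moving)) n_moving <- rep(NA_integer_, n)
  if (is.null(undefined)) undefined <- rep(FALSE, n)
  out <- data.frame(t = t, phi = phi, n_moving = n_moving,
                    undefined = undefined)
  class(out) <- c("order_series", "data.frame")
  attr(out, "dt_sample") <- dt_sample
  out
}

#' Extract the order-parameter series from a trajectory
#'
#' The order parameter is the population mean of the dimensionless
#' velocities, `phi(t) = (1/N) sum_i u_i(t)`; with `moving_only = TRUE` the
#' mean runs over moving particles only (`phi_moving`), and samples with no
#' movers are flagged undefined.
#'
#' @param traj a `swarm_trajectory` from [run_simulation()].
#' @param moving_only use the moving-only order parameter?
#' @return an [order_series()].
#' @export
order_parameter <- function(traj, moving_only = FALSE) {
  s <- traj$series
  if (is.null(s) || nrow(s) == 0) stop("trajectory stores no samples")
  if (moving_only && "phi_moving" %in% names(s)) {
    order_series(s$t, s$phi_moving, n_moving = s$n_moving,
                 undefined = s$n_moving == 0)
  } else if ("phi" %in% names(s)) {
    nm <- if ("n_moving" %in% names(s)) s$n_moving else rep(traj$params$N, nrow(s))
    order_series(s$t, s$phi, n_moving = nm)
  } else {
    stop("trajectory has no scalar order parameter (2D run?); use series columns directly")
  }
}

#' Mean order parameter
#'
#' Time average of `|phi|` after discarding an initial burn-in, skipping
#' undefined samples. Lies in `[0, 1]` for sources with `|u| <= 1`; values
#' near 1 indicate coherent marching, values near 0 disorder.
#'
#' @param series an [order_series()].
#' @param burn_in duration to discard from the start; default 10% of the
#'   observed span.
#' @return the mean order (scalar).
#' @export
mean_order <- function(series, burn_in = NULL) {
  span <- series$t[nrow(series)] - series$t[1]
  if (is.null(burn_in)) burn_in <- 0.1 * span
  if (burn_in >= span) stop("series shorter than burn_in")
  keep <- series$t >= series$t[1] + burn_in & !series$undefined
  mean(abs(series$phi[keep]))
}

#' Discard an initial burn-in from an order series
#'
#' @param series an [order_series()].
#' @param burn_in duration to discard; default 10% of the span.
#' @return the trimmed [order_series()].
#' @export
trim_series <- function(series, burn_in = NULL) {
  span <- series$t[nrow(series)] - series$t[1]
  if (is.null(burn_in)) burn_in <- 0.1 * span
  keep <- series$t >= series$t[1] + burn_in
  out <- series[keep, , drop = FALSE]
  class(out) <- class(series)
  attr(out, "dt_sample") <- attr(series, "dt_sample")
  out
}

#' Metastable-state labelling and switching statistics
#'
#' Labels each sample `A+` when `phi > p`, `A-` when `phi < -p`, `D`
#' (undecided) otherwise. A switch is counted when the series enters one
#' ordered state after most recently residing in the opposite one;
#' intermediate residence in `D` does not count, so re-entering the same
#' side is not a switch (hysteresis rule). Waiting times are the times
#' between consecutive opposite-state entries, and the rate is the number of
#' switches per unit observed time.
#'
#' @param series an [order_series()].
#' @param p order cutoff in (0, 1); 0.7 is the conventional choice.
#' @return an object of class `transition_stats`: a list with `p_cutoff`,
#'   `labels` (factor `A+`/`A-`/`D`), `n_switches`, `total_time`, `rate`,
#'   `waits`, and the `entry_times` of ordered-state entries.
#' @export
transitions <- function(series, p = 0.7) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  phi <- series$phi
  lab <- ifelse(phi > p, 1L, ifelse(phi < -p, -1L, 0L))
  lab[series$undefined] <- 0L
  nz <- which(lab != 0L)
  total_time <- series$t[nrow(series)] - series$t[1]
  if (length(nz) == 0) {
    return(structure(list(p_cutoff = p,
                          labels = factor(rep("D", length(phi)),
                                          levels = c("A+", "A-", "D")),
                          n_switches = 0L, total_time = total_time,
                          rate = 0, waits = numeric(0),
                          entry_times = numeric(0)),
                     class = "transition_stats"))
  }
  labs <- lab[nz]
  entry <- c(TRUE, labs[-1] != labs[-length(labs)])
  entry_idx <- nz[entry]
  entry_times <- series$t[entry_idx]
  waits <- diff(entry_times)
  n_switches <- length(waits)
  labels <- factor(c("D", "A+", "A-")[match(lab, c(0L, 1L, -1L))],
                   levels = c("A+", "A-", "D"))
  structure(list(p_cutoff = p, labels = labels,
                 n_switches = as.integer(n_switches),
                 total_time = total_time,
                 rate = n_switches / total_time,
                 waits = waits, entry_times = entry_times),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("<transition_stats> p =", x$p_cutoff, " switches =", x$n_switches,
      " over", format(x$total_time), "time  rate =", format(x$rate), "\n")
  invisible(x)
}

#' Exponential fit of switching waiting times
#'
#' Maximum-likelihood exponential rate (`1 / mean(waits)`) with a
#' Kolmogorov-Smirnov goodness-of-fit statistic against the fitted
#' exponential. For an ordered swarm behaving as a two-state continuous-time
#' Markov chain the waiting times are exponential and the test should not
#' reject. The plug-in of the estimated rate makes the p-value conservative;
#' ties from discretely sampled waits are tolerated.
#'
#' @param waits positive waiting times (at least 2).
#' @return a list with `rate`, `n`, `statistic` and `p_value`.
#' @export
fit_exponential_waits <- function(waits) {
  if (length(waits) < 2) stop("need at least 2 waiting times")
  rate <- 1 / mean(waits)
  ks <- suppressWarnings(ks.test(waits, "pexp", rate = rate))
  list(rate = rate, n = length(waits),
       statistic = unname(ks$statistic), p_value = ks$p.value)
}

# Pool coarse increments (phi_start, dphi) from one series or a list.
.fd_increments <- function(series, dt_cg) {
  if (inherits(series, "order_series")) series <- list(series)
  phi0 <- numeric(0); dphi <- numeric(0)
  for (s in series) {
    dts <- attr(s, "dt_sample")
    if (is.na(dts)) stop("series too short for increments")
    stride <- dt_cg / dts
    if (abs(stride - round(stride)) > 1e-8)
      stop("dt_cg must be an integer multiple of the sampling interval")
    stride <- as.integer(round(stride))
    if (stride < 1) stop("dt_cg smaller than the sampling interval")
    n <- nrow(s)
    if (n <= stride) next
    i0 <- seq_len(n - stride)
    ok <- !(s$undefined[i0] | s$undefined[i0 + stride])
    phi0 <- c(phi0, s$phi[i0][ok])
    dphi <- c(dphi, (s$phi[i0 + stride] - s$phi[i0])[ok])
  }
  list(phi0 = phi0, dphi = dphi)
}

#' Binned effective drift and diffusion of the order parameter
#'
#' Estimates the drift `F(phi)` and diffusion `D(phi)` of the effective
#' diffusion model `dphi = F(phi) dt + sqrt(2 D(phi)) dW` by conditioning
#' coarse increments on the starting value: increments
#' `phi(t + dt_cg) - phi(t)` are hard-binned by `phi(t)`, and per bin
#' `F = mean(increment) / dt_cg` while `D` is the variance (default) or raw
#' second moment of the increments divided by `2 dt_cg`. The two `D`
#' variants agree as `dt_cg -> 0` and differ by `F^2 dt_cg / 2` at finite
#' coarse steps. Bins with fewer than `min_count` increments are masked
#' invalid rather than extrapolated.
#'
#' @param series an [order_series()] or a list of them (increments are
#'   pooled and never span series boundaries — the many-short-trajectories
#'   protocol).
#' @param dt_cg coarse time increment; must be an integer multiple of the
#'   sampling interval. A natural scale is the lap time `L / v` of the ring.
#' @param n_bins number of uniform bins over `phi_range`.
#' @param method `"variance"` or `"second_moment"`.
#' @param min_count minimum increments per valid bin.
#' @param phi_range bin range for the starting order value.
#' @return an object of class `c("fd_estimate", "data.frame")` with columns
#'   `bin_center`, `F`, `D`, `count`, `valid`, and attributes `dt_cg` and
#'   `method`.
#' @export
estimate_FD <- function(series, dt_cg, n_bins = 51,
                        method = c("variance", "second_moment"),
                        min_count = 100, phi_range = c(-1.2, 1.2)) {
  method <- match.arg(method)
  inc <- .fd_increments(series, dt_cg)
  breaks <- seq(phi_range[1], phi_range[2], length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(inc$phi0, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= n_bins
  bin <- bin[ok]; dphi <- inc$dphi[ok]
  cnt <- tabulate(bin, nbins = n_bins)
  Fv <- rep(NA_real_, n_bins); Dv <- rep(NA_real_, n_bins)
  s1 <- vapply(seq_len(n_bins), function(b) sum(dphi[bin == b]), numeric(1))
  s2 <- vapply(seq_len(n_bins), function(b) sum(dphi[bin == b]^2), numeric(1))
  has <- cnt > 0
  mu <- ifelse(has, s1 / pmax(cnt, 1), NA_real_)
  Fv[has] <- mu[has] / dt_cg
  if (method == "variance") {
    v <- ifelse(cnt > 1, (s2 - cnt * mu^2) / (cnt - 1), NA_real_)
    Dv <- v / (2 * dt_cg)
  } else {
    Dv <- ifelse(has, s2 / pmax(cnt, 1) / (2 * dt_cg), NA_real_)
  }
  valid <- cnt >= min_count & !is.na(Fv) & !is.na(Dv)
  out <- data.frame(bin_center = centers, F = Fv, D = Dv, count = cnt,
                    valid = valid)
  class(out) <- c("fd_estimate", "data.frame")
  attr(out, "dt_cg") <- dt_cg
  attr(out, "method") <- method
  out
}

#' Classify the fixed points of an estimated drift
#'
#' A fixed point sits at every sign change of the estimated drift between
#' adjacent valid bins, located by linear interpolation. The point is stable
#' when `F` passes from positive to negative with increasing `phi` (the
#' order parameter is pulled back), unstable for the opposite crossing.
#' Stable zeros are the metastable states of the coarse-grained dynamics.
#'
#' @param est an [estimate_FD()] result with at least 2 valid adjacent bins.
#' @return a data frame with columns `location` and `stability`
#'   (`"stable"`/`"unstable"`); zero rows if no valid sign change exists.
#' @export
classify_fixed_points <- function(est) {
  v <- which(est$valid)
  loc <- numeric(0); stab <- character(0)
  if (length(v) >= 2) {
    for (k in seq_len(length(v) - 1)) {
      i <- v[k]; j <- v[k + 1]
      if (j != i + 1) next # only adjacent valid bins
      Fi <- est$F[i]; Fj <- est$F[j]
      if (is.na(Fi) || is.na(Fj) || Fi * Fj >= 0) next
      xi <- est$bin_center[i]; xj <- est$bin_center[j]
      loc <- c(loc, xi + (0 - Fi) * (xj - xi) / (Fj - Fi))
      stab <- c(stab, if (Fi > 0) "stable" else "unstable")
    }
  }
  data.frame(location = loc, stability = stab)
}

#' Drift / diffusion function descriptors for the synthetic generator
#'
#' Named families evaluated in compiled code by [synth_sde()]:
#' zero drift, constant drift `c`, mean-reverting (Ornstein-Uhlenbeck) drift
#' `-theta * phi`, and double-well drift `a * phi - b * phi^3` (stable wells
#' at `+-sqrt(a/b)`); constant diffusion `D0`.
#'
#' @param c,theta,a,b,D0 family parameters.
#' @return a descriptor list with components `kind` and `par`.
#' @name sde_specs
NULL

#' @rdname sde_specs
#' @export
drift_zero <- function() list(kind = "zero", par = numeric(0))

#' @rdname sde_specs
#' @export
drift_const <- function(c) list(kind = "const", par = c)

#' @rdname sde_specs
#' @export
drift_ou <- function(theta) list(kind = "ou", par = theta)

#' @rdname sde_specs
#' @export
drift_double_well <- function(a = 1, b = 1) list(kind = "double_well", par = c(a, b))

#' @rdname sde_specs
#' @export
diffusion_const <- function(D0) {
  if (D0 < 0) stop("D0 must be non-negative")
  list(kind = "const", par = D0)
}

#' Synthetic effective-SDE path (estimator oracle)
#'
#' Euler-Maruyama path of `dphi = F(phi) dt + sqrt(2 D(phi)) dW` for a given
#' drift and diffusion specification, used to validate [estimate_FD()]
#' against known generating functions. Descriptor specs (see [sde_specs])
#' run in compiled code; plain R functions are also accepted (slower loop).
#'
#' @param drift a descriptor from [sde_specs] or a function `F(phi)`.
#' @param diffusion a descriptor ([diffusion_const()]) or a function
#'   `D(phi)`.
#' @param T total duration.
#' @param dt integration step.
#' @param seed integer seed.
#' @param phi0 initial value.
#' @param sample_every record every this many steps.
#' @return an [order_series()].
#' @export
synth_sde <- function(drift, diffusion, T, dt, seed, phi0 = 0,
                      sample_every = 1) {
  n_steps <- as.integer(round(T / dt))
  if (n_steps < 1) stop("T must cover at least one step")
  set.seed(seed)
  if (is.list(drift) && is.list(diffusion)) {
    kinds <- c(zero = 0L, const = 1L, ou = 2L, double_well = 3L)
    if (!drift$kind %in% names(kinds)) stop("unknown drift kind")
    if (diffusion$kind != "const") stop("diffusion descriptor must be constant")
    res <- synth_sde_cpp(kinds[[drift$kind]], as.numeric(drift$par),
                         as.numeric(diffusion$par), phi0,
                         n_steps, dt, as.integer(sample_every))
    return(order_series(res$t, res$phi))
  }
  Ffun <- if (is.function(drift)) drift else .spec_fun(drift)
  Dfun <- if (is.function(diffusion)) diffusion else .spec_fun(diffusion)
  phi <- phi0
  n_samp <- n_steps %/% sample_every + 1
  ts <- numeric(n_samp); ph <- numeric(n_samp)
  ts[1] <- 0; ph[1] <- phi
  k <- 2
  for (step in seq_len(n_steps)) {
    Dv <- Dfun(phi)
    phi <- phi + Ffun(phi) * dt +
      (if (Dv > 0) sqrt(2 * Dv * dt) * rnorm(1) else 0)
    if (step %% sample_every == 0) {
      ts[k] <- step * dt; ph[k] <- phi; k <- k + 1
    }
  }
  order_series(ts, ph)
}

.spec_fun <- function(spec) {
  switch(spec$kind,
         zero = function(phi) 0,
         const = function(phi) spec$par,
         ou = function(phi) -spec$par * phi,
         double_well = function(phi) spec$par[1] * phi - spec$par[2] * phi^3,
         stop("unknown spec kind"))
}

#' Ensemble drift/diffusion estimate from many short runs
#'
#' Materialises the many-short-trajectories protocol for the Fig.-3-style
#' effective drift/diffusion profiles: for each initial order value in
#' `phi0_grid` and each replicate, a fresh simulation of exactly one coarse
#' increment `dt_cg` is run from an initial condition with velocities spread
#' around that value, and all increments are pooled into [estimate_FD()].
#' This populates every order bin evenly, including the rarely visited
#' transition region of strongly bistable models.
#'
#' @param model,params as in [run_simulation()].
#' @param dt_cg coarse increment (rounded to a whole number of steps).
#' @param phi0_grid initial order values to seed.
#' @param replicates runs per grid value.
#' @param seed base seed; run `k` uses `seed + k`.
#' @param moving_only analyse the moving-only order parameter?
#' @param spread half-width of the initial velocity draw around each
#'   `phi0`.
#' @param ... passed on to [estimate_FD()] (`n_bins`, `min_count`, `method`,
#'   `phi_range`).
#' @return an `fd_estimate`.
#' @export
fd_ensemble <- function(model, params, dt_cg, phi0_grid, replicates,
                        seed, moving_only = FALSE, spread = 0.3, ...) {
  n_steps <- as.integer(round(dt_cg / params$dt))
  if (n_steps < 1) stop("dt_cg must cover at least one step")
  dt_cg_eff <- n_steps * params$dt
  runs <- vector("list", length(phi0_grid) * replicates)
  k <- 0L
  for (phi0 in phi0_grid) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      set.seed(seed + k)
      init <- init_swarm(params, phi0 = phi0, spread = spread)
      # separate stream for the dynamics so init and noise draws do not overlap
      traj <- run_simulation(model, params, n_steps = n_steps,
                             sample_every = n_steps,
                             seed = (seed + k) %% 1000000000L + 1000000000L,
                             init = init)
      runs[[k]] <- order_parameter(traj, moving_only = moving_only)
    }
  }
  estimate_FD(runs, dt_cg = dt_cg_eff, ...)
}
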