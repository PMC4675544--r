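#' Parameter set for the 1D alignment-model family
#'
#' Builds a validated parameter record shared by the Czirok (continuous and
#' discrete), individual-choice and Buhl models on a periodic ring. Exactly
#' one of `L` or `rho` may be omitted; the other is derived from `N` so that
#' `rho * L == N` holds exactly. The noise amplitude can be given either as
#' the uniform-noise width `eta` (noise drawn from `U[-eta/2, eta/2]`) or as
#' the standard deviation `sigma`; the two are tied by `sigma^2 = eta^2 / 12`,
#' the variance of that uniform distribution.
#'
#' @param N number of particles (>= 1).
#' @param L ring length (> 0). Derived from `rho` if missing.
#' @param rho linear density `N / L`. Derived from `L` if missing.
#' @param v speed scale (length per unit time).
#' @param eta uniform-noise width (dimensionless). Default 2 when neither
#'   `eta` nor `sigma` is given, the reference simulation setting.
#' @param sigma noise standard deviation; alternative to `eta`.
#' @param delta interaction range (length units).
#' @param dt integration step. `dt = 1` gives the discrete models; small `dt`
#'   approximates the continuous dynamics. Steps above 2 are rejected: the
#'   velocity relaxation has unit rate, so the explicit Euler update is
#'   unstable beyond that.
#' @param alpha persistence weight in `[0, 1]`: the retain probability of the
#'   individual-choice model, or the own-velocity weight of the Buhl model.
#' @param update_mode `"synchronous"` (all particles updated from the state at
#'   the step start) or `"asynchronous"` (N randomly chosen particles updated
#'   sequentially per step, with repetitions).
#' @param neighbor_mode `"local_mean"` or `"single_random_neighbor"` (align
#'   with one uniformly chosen neighbour instead of the local average).
#' @param noise_kind `"uniform"` or `"gaussian"`; both have variance
#'   `sigma^2`.
#' @return an object of class `model_params`.
#' @examples
#' p <- model_params(N = 100, rho = 3.2) # reference high-density setting
#' p$L
#' @export
model_params <- function(N, L = NULL, rho = NULL, v = 0.1,
                         eta = NULL, sigma = NULL, delta = 1, dt = 1,
                         alpha = 0,
                         update_mode = c("synchronous", "asynchronous"),
                         neighbor_mode = c("local_mean", "single_random_neighbor"),
                         noise_kind = c("uniform", "gaussian")) {
  update_mode <- match.arg(update_mode)
  neighbor_mode <- match.arg(neighbor_mode)
  noise_kind <- match.arg(noise_kind)
  if (length(N) != 1 || N < 1 || N != round(N)) stop("N must be a positive integer")
  N <- as.integer(N)
  if (is.null(L) && is.null(rho)) stop("give L or rho")
  if (is.null(L)) L <- N / rho
  if (is.null(rho)) rho <- N / L
  if (L <= 0) stop("L must be positive")
  if (abs(rho * L - N) > 1e-8 * N) stop("inconsistent L and rho: rho * L must equal N")
  rho <- N / L # make the identity exact
  if (is.null(eta) && is.null(sigma)) eta <- 2
  if (is.null(sigma)) sigma <- eta / sqrt(12)
  if (is.null(eta)) eta <- sigma * sqrt(12)
  if (abs(sigma - eta / sqrt(12)) > 1e-10 * max(1, sigma))
    stop("inconsistent eta and sigma: sigma^2 must equal eta^2 / 12")
  if (sigma < 0) stop("sigma must be non-negative")
  if (delta <= 0) stop("delta must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (dt > 2) stop("dt > 2 rejected: explicit Euler update of the unit-rate velocity relaxation is unstable")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(list(N = N, L = L, rho = rho, v = v, eta = eta, sigma = sigma,
                 delta = delta, dt = dt, alpha = alpha,
                 update_mode = update_mode, neighbor_mode = neighbor_mode,
                 noise_kind = noise_kind),
            class = "model_params")
}

#' Reference simulation parameter set
#'
#' The shared defaults used throughout the comparative runs: `N = 100`,
#' `eta = 2`, `delta = 1`, `v = 0.1`, at a chosen density.
#'
#' @param rho linear density.
#' @param ... further arguments passed to [model_params()].
#' @return a `model_params` object.
#' @export
reference_params <- function(rho = 3.2, ...) {
  model_params(N = 100, rho = rho, v = 0.1, eta = 2, delta = 1, ...)
}

#' Parameter set for the 1D three-zone model
#'
#' Extends [model_params()] with the alignment-zone radius `r2`
#' (`0 < r2 < delta`). The avoidance zone of the full three-zone scheme is
#' deliberately absent: in one dimension on a ring, avoidance has no sensible
#' counterpart. Particles align with a randomly chosen neighbour closer than
#' `r2` and are attracted towards neighbours between `r2` and `delta`.
#'
#' @param ... arguments for [model_params()].
#' @param r2 alignment-zone radius (length units).
#' @return an object of class `c("bode_params", "model_params")`.
#' @export
bode_params <- function(..., r2 = 0.5) {
  p <- model_params(...)
  if (r2 <= 0 || r2 >= p$delta) stop("r2 must satisfy 0 < r2 < delta")
  p$r2 <- r2
  class(p) <- c("bode_params", class(p))
  p
}

#' Parameter set for the pause-and-go model
#'
#' Two-state (walk/stand) agents: a walker stops at rate `k_walk`; a stander
#' starts at rate `k_stand0`, jumping to `k_stand1` once the number of moving
#' neighbours within `delta` reaches `n_c_moving`. A particle that starts
#' walking aligns with the local order among moving neighbours with
#' probability `alpha(x) = clip(a0 + a1 * |x|, 0, 1)`, where `x` is that
#' local order; otherwise it retains its heading (plus noise). Rates are per
#' unit time and are converted to per-step probabilities with the exact
#' exponential mapping `1 - exp(-k * dt)`.
#'
#' @param ... arguments for [model_params()]; `dt` defaults to 0.1 here.
#' @param k_walk stop rate of a walker (1/time).
#' @param k_stand0,k_stand1 low/high start rates of a stander (1/time).
#' @param n_c_moving moving-neighbour threshold (>= 1) at which the start
#'   rate jumps; the threshold is inclusive.
#' @param a0,a1 intercept and slope of the alignment probability; `a1 >= 0`
#'   so that more ordered crowds are joined more readily.
#' @param realign_walkers if `TRUE`, walking particles re-evaluate the
#'   alignment rule every step instead of only at stand-to-walk transitions.
#'   A diagnostic variant: with stops disabled it embeds the always-moving
#'   alignment models as a limiting case.
#' @param dt integration step (default 0.1).
#' @return an object of class `c("png_params", "model_params")`.
#' @export
png_params <- function(..., k_walk = 0.2, k_stand0 = 0.05, k_stand1 = 1,
                       n_c_moving = 2, a0 = 0.3, a1 = 0.7,
                       realign_walkers = FALSE, dt = 0.1) {
  p <- model_params(..., dt = dt)
  if (k_walk < 0) stop("k_walk must be non-negative")
  if (k_stand0 < 0 || k_stand1 < k_stand0)
    stop("start rates must satisfy 0 <= k_stand0 <= k_stand1")
  if (n_c_moving < 1 || n_c_moving != round(n_c_moving))
    stop("n_c_moving must be a positive integer")
  if (a1 < 0) stop("a1 must be non-negative (alignment probability increasing in order)")
  p$k_walk <- k_walk
  p$k_stand0 <- k_stand0
  p$k_stand1 <- k_stand1
  p$n_c_moving <- as.integer(n_c_moving)
  p$a0 <- a0
  p$a1 <- a1
  p$realign_walkers <- isTRUE(realign_walkers)
  class(p) <- c("png_params", class(p))
  p
}

#' Parameter set for the escape-and-pursuit model
#'
#' Langevin dynamics with a social force: particles accelerate towards
#' neighbours receding in front (pursuit, strength `chi_p`) and away from
#' neighbours approaching from behind (escape, strength `chi_e`), within an
#' interaction radius `R`. The native geometry is a periodic square of side
#' `box`; a diagnostic 1D variant runs on a ring of length `box`.
#'
#' @param N number of particles.
#' @param box side of the periodic square (or ring length in 1D).
#' @param gamma friction coefficient (1/time).
#' @param diff diffusion coefficient `D` (velocity^2 per time).
#' @param chi_e,chi_p escape and pursuit strengths (>= 0).
#' @param R interaction radius (length units).
#' @param v speed scale.
#' @param dt integration step.
#' @return an object of class `ep_params`.
#' @export
ep_params <- function(N, box = 10, gamma = 1, diff = 0.1,
                      chi_e = 1, chi_p = 1, R = 1, v = 1, dt = 0.01) {
  if (length(N) != 1 || N < 1 || N != round(N)) stop("N must be a positive integer")
  if (box <= 0) stop("box must be positive")
  if (gamma < 0) stop("gamma must be non-negative")
  if (diff < 0) stop("diff must be non-negative")
  if (chi_e < 0 || chi_p < 0) stop("interaction strengths must be non-negative")
  if (R <= 0) stop("R must be positive")
  if (dt <= 0) stop("dt must be positive")
  structure(list(N = as.integer(N), box = box, gamma = gamma, diff = diff,
                 chi_e = chi_e, chi_p = chi_p, R = R, v = v, dt = dt),
            class = "ep_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<", class(x)[1], "> N =", x$N, " L =", format(x$L), " rho =", format(x$rho),
      "\n  v =", x$v, " eta =", format(x$eta), " sigma =", format(x$sigma),
      " delta =", x$delta, " dt =", x$dt, " alpha =", x$alpha, "\n")
  cat("  update:", x$update_mode, " neighbours:", x$neighbor_mode,
      " noise:", x$noise_kind, "\n")
  extra <- setdiff(names(x), c("N", "L", "rho", "v", "eta", "sigma", "delta",
                               "dt", "alpha", "update_mode", "neighbor_mode",
                               "noise_kind"))
  if (length(extra))
    cat("  ", paste(extra, vapply(x[extra], format, ""), sep = " = ",
                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ep_params <- function(x, ...) {
  cat("<ep_params> N =", x$N, " box =", x$box, " gamma =", x$gamma,
      " D =", x$diff, "\n  chi_e =", x$chi_e, " chi_p =", x$chi_p,
      " R =", x$R, " v =", x$v, " dt =", x$dt, "\n")
  invisible(x)
}
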