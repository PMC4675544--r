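# Pause-and-go model: two-state (walk/stand) agents with rate-driven
# switching, movement-gated alignment, and moving-only averaging.

#' Start rate of a standing particle
#'
#' Step function of the number of moving neighbours: the low rate `k_stand0`
#' below the threshold `n_c_moving`, the high rate `k_stand1` at or above it
#' (the threshold is inclusive). Non-decreasing in `n_moving`: local movement
#' raises the probability that a stander starts walking.
#'
#' @param n_moving number of moving neighbours within the interaction range.
#' @param params a [png_params()] object.
#' @return a rate (1/time), vectorised over `n_moving`.
#' @export
stand_rate <- function(n_moving, params) {
  if (any(n_moving < 0)) stop("n_moving must be non-negative")
  ifelse(n_moving >= params$n_c_moving, params$k_stand1, params$k_stand0)
}

#' Alignment probability of a starting particle
#'
#' Linear, increasing function of the magnitude of the local order among
#' moving neighbours, clipped to `[0, 1]`:
#' `alpha(x) = clip(a0 + a1 * |x|, 0, 1)`. Animals join ordered crowds more
#' readily than disordered ones; the magnitude is used so that clockwise and
#' counter-clockwise order are treated symmetrically.
#'
#' @param local_order local order value in `[-1, 1]` (small overshoot
#'   tolerated).
#' @param params a [png_params()] object.
#' @return a probability, vectorised over `local_order`.
#' @export
alignment_probability <- function(local_order, params) {
  pmin(1, pmax(0, params$a0 + params$a1 * abs(local_order)))
}

#' Order parameter over moving particles
#'
#' Mean dimensionless velocity of the moving particles only; standers do not
#' contribute. When no particle is moving the value is 0 and the attribute
#' `undefined` is `TRUE` (downstream estimators skip flagged samples).
#'
#' @param state a [swarm_state()].
#' @return a scalar with logical attribute `undefined`.
#' @export
phi_moving <- function(state) {
  n <- sum(state$moving)
  if (n == 0) return(structure(0, undefined = TRUE))
  structure(mean(state$u[state$moving]), undefined = FALSE)
}

#' One step of the pause-and-go model
#'
#' From the state at the start of the step, each walker stops with
#' probability `1 - exp(-k_walk * dt)` and each stander starts with
#' probability `1 - exp(-k * dt)` where `k = stand_rate(n_moving)` counts the
#' moving neighbours within `delta` (standing particles are ignored in
#' counts and averages). A particle that starts walking aligns with
#' probability [alignment_probability()] of the local moving order `m`,
#' updating `u <- u + (G(m) - u) * dt + sqrt(dt) * xi`; otherwise it retains
#' its heading plus the same noise term. Walking particles keep their heading
#' fixed (unless `realign_walkers` is set). Particles moving after the
#' transition advance by `v * u * dt`; standers do not move.
#'
#' Draw protocol per step, in particle order: `N` event uniforms (stop/start
#' tests), `N` alignment-choice uniforms, `N` noise variates.
#'
#' @param state a [swarm_state()] (the `moving` flags are meaningful here).
#' @param params a [png_params()] object.
#' @param draws optional list with components `event`, `choice`, `xi`; drawn
#'   internally when `NULL`.
#' @return the updated `swarm_state`.
#' @export
step_png <- function(state, params, draws = NULL) {
  N <- state$N; dt <- params$dt; sqdt <- sqrt(dt)
  if (is.null(draws)) {
    draws <- list(event = runif(N), choice = runif(N),
                  xi = if (params$noise_kind == "uniform")
                    runif(N, -params$eta / 2, params$eta / 2)
                  else rnorm(N, 0, params$sigma))
  }
  d <- abs(outer(state$x, state$x, "-"))
  d <- pmin(d, state$L - d)
  adj <- d <= params$delta
  diag(adj) <- FALSE
  adj <- adj & rep(state$moving, each = N)
  cnt <- rowSums(adj)
  m <- ifelse(cnt > 0, as.vector(adj %*% state$u) / cnt, 0)

  p_stop <- 1 - exp(-params$k_walk * dt)
  p_start <- 1 - exp(-stand_rate(cnt, params) * dt)
  mov_new <- ifelse(state$moving, draws$event >= p_stop, draws$event < p_start)

  starter <- (!state$moving & mov_new) |
    (params$realign_walkers & state$moving & mov_new)
  a <- alignment_probability(m, params)
  u <- state$u
  align <- starter & (draws$choice < a)
  keep <- starter & !align
  u[align] <- u[align] + (g_function(m[align]) - u[align]) * dt +
    sqdt * draws$xi[align]
  u[keep] <- u[keep] + sqdt * draws$xi[keep]

  x <- state$x
  x[mov_new] <- ring_wrap(x[mov_new] + params$v * u[mov_new] * dt, state$L)
  swarm_state(x, u, L = state$L, t = state$t + dt, moving = mov_new)
}
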