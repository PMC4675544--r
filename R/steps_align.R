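# Single-step updates of the alignment-model family, implemented directly in
# R. run_simulation() uses the compiled loop in src/core.cpp; these functions
# define the per-step semantics, are used in tests, and accept explicitly
# supplied random draws so that different models can be coupled on a common
# random-number stream.

#' Draw one step's worth of random variates for the alignment family
#'
#' All synchronous alignment models consume the same blocks per step, in this
#' order: `N` choice uniforms, then (single-random-neighbour mode only) `N`
#' pick uniforms, then `N` noise variates, each block in particle order. A
#' model that does not use a block still consumes it, so trajectories of
#' different models started from the same seed see identical noise (common
#' random numbers).
#'
#' @param params a `model_params` object.
#' @return a list with components `choice`, `pick` (or `NULL`), and `xi`.
#' @export
draw_step_noise <- function(params) {
  N <- params$N
  choice <- runif(N)
  pick <- if (params$neighbor_mode == "single_random_neighbor") runif(N) else NULL
  xi <- if (params$noise_kind == "uniform")
    runif(N, -params$eta / 2, params$eta / 2)
  else rnorm(N, 0, params$sigma)
  list(choice = choice, pick = pick, xi = xi)
}

# Alignment target per particle for the synchronous family.
.align_target <- function(state, params, include_self, pick = NULL) {
  if (params$neighbor_mode == "local_mean") {
    .neighbour_means(state$x, state$u, state$L, params$delta,
                     include_self = include_self)
  } else {
    nbr <- .neighbour_lists(state$x, state$L, params$delta)
    vapply(seq_len(state$N), function(i) {
      k <- length(nbr[[i]])
      if (k == 0) return(if (include_self) state$u[i] else 0)
      state$u[nbr[[i]][floor(pick[i] * k) + 1]]
    }, numeric(1))
  }
}

# Shared synchronous-step skeleton: positions advance with the pre-update
# velocities; `velocity_rule(u, m, draws)` returns the new velocities.
.step_sync <- function(state, params, draws, include_self, velocity_rule) {
  if (is.null(draws)) draws <- draw_step_noise(params)
  m <- .align_target(state, params, include_self, draws$pick)
  x_new <- ring_wrap(state$x + params$v * state$u * params$dt, state$L)
  u_new <- velocity_rule(state$u, m, draws)
  swarm_state(x_new, u_new, L = state$L, t = state$t + params$dt,
              moving = state$moving)
}

# Asynchronous variant: N sequential sub-updates of randomly chosen
# particles. Draw order per sub-update: index, choice, (pick), noise.
.step_async <- function(state, params, include_self, velocity_rule_1) {
  N <- state$N
  x <- state$x; u <- state$u
  single <- params$neighbor_mode == "single_random_neighbor"
  for (k in seq_len(N)) {
    i <- min(N, floor(runif(1) * N) + 1)
    ch <- runif(1)
    sel <- ring_distance(x[i], x, state$L) <= params$delta
    sel[i] <- FALSE
    js <- which(sel)
    if (!single) {
      mi <- if (include_self) (sum(u[js]) + u[i]) / (length(js) + 1)
            else if (length(js) > 0) mean(u[js]) else 0
    } else {
      mi <- if (length(js) > 0) u[js[floor(runif(1) * length(js)) + 1]]
            else if (include_self) u[i] else 0
    }
    xi <- if (params$noise_kind == "uniform")
      runif(1, -params$eta / 2, params$eta / 2) else rnorm(1, 0, params$sigma)
    x[i] <- ring_wrap(x[i] + params$v * u[i] * params$dt, state$L)
    u[i] <- velocity_rule_1(u[i], mi, ch, xi)
  }
  swarm_state(x, u, L = state$L, t = state$t + params$dt, moving = state$moving)
}

#' One step of the Czirok alignment model
#'
#' Euler-Maruyama update of the alignment dynamics: positions advance by
#' `v * u * dt` (periodic wrap), and velocities relax towards
#' `G(<u>_i)`, the response to the self-inclusive local average, plus noise:
#' `u <- u + (G(<u>_i) - u) * dt + sqrt(dt) * xi` with `xi` of variance
#' `sigma^2`. With `dt = 1` this reduces to the discrete model
#' `u <- G(<u>_i) + xi`.
#'
#' @param state a [swarm_state()].
#' @param params a [model_params()] object.
#' @param draws optional pre-drawn variates from [draw_step_noise()]; drawn
#'   internally when `NULL`.
#' @return the updated `swarm_state`.
#' @export
step_czirok <- function(state, params, draws = NULL) {
  dt <- params$dt; sqdt <- sqrt(dt)
  if (params$update_mode == "asynchronous")
    return(.step_async(state, params, TRUE,
                       function(u, m, ch, xi) u + (g_function(m) - u) * dt + sqdt * xi))
  .step_sync(state, params, draws, include_self = TRUE,
             function(u, m, draws) u + (g_function(m) - u) * dt + sqdt * draws$xi)
}

#' One step of the individual-choice model
#'
#' Each particle independently retains its velocity with probability `alpha`
#' (keeping `u` exactly — persistence is a noiseless decision); otherwise it
#' aligns exactly as in [step_czirok()], noise included. With `alpha = 0` the
#' align branch always fires, reproducing the Czirok update draw-for-draw;
#' the unused choice uniforms are still consumed, so the two models can be
#' compared on a common noise stream.
#'
#' @inheritParams step_czirok
#' @return the updated `swarm_state`.
#' @export
step_individual_choice <- function(state, params, draws = NULL) {
  dt <- params$dt; sqdt <- sqrt(dt); alpha <- params$alpha
  if (params$update_mode == "asynchronous")
    return(.step_async(state, params, TRUE,
                       function(u, m, ch, xi)
                         if (ch < alpha) u
                         else u + (g_function(m) - u) * dt + sqdt * xi))
  .step_sync(state, params, draws, include_self = TRUE,
             function(u, m, draws) {
               retain <- draws$choice < alpha
               ifelse(retain, u,
                      u + (g_function(m) - u) * dt + sqdt * draws$xi)
             })
}

#' One step of the Buhl model
#'
#' Discrete-time update weighting a particle's own velocity against the
#' response to the self-excluded local average:
#' `u <- alpha * u + (1 - alpha) * G(<u>_i^-) + xi`, where `<u>_i^-`
#' averages the neighbours of `i` excluding `i` itself (0 for a lone
#' particle). Defined for `dt = 1` only.
#'
#' @inheritParams step_czirok
#' @return the updated `swarm_state`.
#' @export
step_buhl <- function(state, params, draws = NULL) {
  if (params$dt != 1) stop("the Buhl update is a discrete-time rule; use dt = 1")
  alpha <- params$alpha
  if (params$update_mode == "asynchronous")
    return(.step_async(state, params, FALSE,
                       function(u, m, ch, xi) alpha * u + (1 - alpha) * g_function(m) + xi))
  .step_sync(state, params, draws, include_self = FALSE,
             function(u, m, draws) alpha * u + (1 - alpha) * g_function(m) + draws$xi)
}

#' One step of the 1D three-zone model
#'
#' Asynchronous by construction: per time step, `N` sub-updates each choose a
#' uniform-random particle `i`; if `i` has neighbours within `delta`, a
#' uniform-random neighbour `k` is chosen and `u_i` set to `G(u_k)` when `k`
#' lies within the alignment radius `r2`, or to the bounded attraction
#' response `G(sgn(dx) * (d - r2) / (delta - r2))` (with `dx` the
#' minimal-image displacement towards `k` and `d = |dx|`) when `k` lies in
#' the attraction zone. The chosen particle then advances by `v * u_i * dt`.
#'
#' @param state a [swarm_state()].
#' @param params a [bode_params()] object.
#' @return the updated `swarm_state`.
#' @export
step_bode <- function(state, params) {
  N <- state$N
  x <- state$x; u <- state$u
  for (k in seq_len(N)) {
    i <- min(N, floor(runif(1) * N) + 1)
    sel <- ring_distance(x[i], x, state$L) <= params$delta
    sel[i] <- FALSE
    js <- which(sel)
    if (length(js) > 0) {
      kk <- js[floor(runif(1) * length(js)) + 1]
      d <- ring_distance(x[i], x[kk], state$L)
      if (d <= params$r2) {
        u[i] <- g_function(u[kk])
      } else {
        dx <- ring_displacement(x[i], x[kk], state$L)
        u[i] <- g_function(sign(dx) * (d - params$r2) / (params$delta - params$r2))
      }
    }
    x[i] <- ring_wrap(x[i] + params$v * u[i] * params$dt, state$L)
  }
  swarm_state(x, u, L = state$L, t = state$t + params$dt, moving = state$moving)
}
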