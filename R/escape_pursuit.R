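# Escape-and-pursuit social-force model (2D, with a diagnostic 1D variant).

#' Classify a neighbour pair for the escape-and-pursuit interaction
#'
#' Neighbour `j` of focal particle `i` is front or back according to the sign
#' of `u_i . rhat_ji` (the focal heading projected on the separation
#' direction), and approaching or receding according to the sign of
#' `u_ji . rhat_ji` (the relative velocity projected likewise). Strict
#' inequalities are used (Heaviside convention `H(0) = 0`), so exactly
#' perpendicular or exactly co-moving pairs fall in no interacting class.
#' Pairs farther apart than `R` are `out_of_range`; a coincident pair is
#' `degenerate` and contributes no force.
#'
#' @param state a [swarm_state_2d()].
#' @param i,j particle indices, `i != j`.
#' @param params an [ep_params()] object.
#' @return one of `"front_approaching"`, `"front_receding"`,
#'   `"back_approaching"`, `"back_receding"`, `"neutral"`, `"out_of_range"`,
#'   `"degenerate"`.
#' @export
classify_pair <- function(state, i, j, params) {
  if (i == j) stop("i and j must differ")
  dx <- ring_displacement(state$pos[i, ], state$pos[j, ], state$box)
  r <- sqrt(sum(dx^2))
  if (r == 0) return("degenerate")
  if (r > params$R) return("out_of_range")
  rhat <- dx / r
  pu <- sum(state$vel[i, ] * rhat)
  pdu <- sum((state$vel[j, ] - state$vel[i, ]) * rhat)
  if (pu == 0 || pdu == 0) return("neutral")
  paste0(if (pu > 0) "front" else "back", "_",
         if (pdu < 0) "approaching" else "receding")
}

#' Escape-and-pursuit social force on one particle
#'
#' Sum of the pursuit and escape terms. Pursuit averages the projected
#' relative velocities `(u_ji . rhat_ji) rhat_ji` over front-receding
#' neighbours within `R` and scales by `chi_p`; escape does the same over
#' back-approaching neighbours scaled by `chi_e`. Each class is normalised by
#' its own neighbour count. Front-approaching and back-receding neighbours
#' are ignored.
#'
#' @param state a [swarm_state_2d()].
#' @param i focal particle index.
#' @param params an [ep_params()] object.
#' @return a length-2 force vector (acceleration units).
#' @export
social_force <- function(state, i, params) {
  fp <- c(0, 0); fe <- c(0, 0); np <- 0L; ne <- 0L
  for (j in seq_len(state$N)) {
    if (j == i) next
    cls <- classify_pair(state, i, j, params)
    if (cls != "front_receding" && cls != "back_approaching") next
    dx <- ring_displacement(state$pos[i, ], state$pos[j, ], state$box)
    r <- sqrt(sum(dx^2))
    rhat <- dx / r
    pdu <- sum((state$vel[j, ] - state$vel[i, ]) * rhat)
    if (cls == "front_receding") { fp <- fp + pdu * rhat; np <- np + 1L }
    else { fe <- fe + pdu * rhat; ne <- ne + 1L }
  }
  f <- c(0, 0)
  if (np > 0) f <- f + params$chi_p * fp / np
  if (ne > 0) f <- f + params$chi_e * fe / ne
  f
}

#' One step of the 2D escape-and-pursuit model
#'
#' Euler-Maruyama update of the Langevin dynamics
#' `du = (-gamma * u + F_social) dt + sqrt(2 D dt) * xi` with isotropic
#' standard-normal `xi` (drawn per particle, x-component then y-component);
#' positions advance by `v * u * dt` with the pre-update velocities and wrap
#' in the periodic box.
#'
#' @param state a [swarm_state_2d()].
#' @param params an [ep_params()] object.
#' @return the updated `swarm_state_2d`.
#' @export
step_ep <- function(state, params) {
  N <- state$N; dt <- params$dt
  f <- t(vapply(seq_len(N), function(i) social_force(state, i, params),
                numeric(2)))
  xi <- matrix(rnorm(2 * N), ncol = 2, byrow = TRUE)
  pos <- ring_wrap(state$pos + params$v * state$vel * dt, state$box)
  vel <- state$vel + (-params$gamma * state$vel + f) * dt +
    sqrt(2 * params$diff * dt) * xi
  swarm_state_2d(pos, vel, box = state$box, t = state$t + dt)
}

#' Escape-and-pursuit force in the 1D variant
#'
#' Same gating logic projected onto the ring: the separation direction is the
#' sign of the minimal-image displacement. A structural consequence of the
#' gates is that a pair with opposite-signed velocities never exerts a mutual
#' force, so clockwise and counter-clockwise groups evolve independently.
#'
#' @param state a [swarm_state()].
#' @param i focal particle index.
#' @param params an [ep_params()] object (`box` is the ring length).
#' @return a scalar force.
#' @export
social_force_1d <- function(state, i, params) {
  f <- 0; np <- 0L; ne <- 0L; sp <- 0; se <- 0
  for (j in seq_len(state$N)) {
    if (j == i) next
    dx <- ring_displacement(state$x[i], state$x[j], params$box)
    r <- abs(dx)
    if (r == 0 || r > params$R) next
    rhat <- sign(dx)
    pu <- state$u[i] * rhat
    pdu <- (state$u[j] - state$u[i]) * rhat
    if (pu > 0 && pdu > 0) { sp <- sp + pdu * rhat; np <- np + 1L }
    else if (pu < 0 && pdu < 0) { se <- se + pdu * rhat; ne <- ne + 1L }
  }
  if (np > 0) f <- f + params$chi_p * sp / np
  if (ne > 0) f <- f + params$chi_e * se / ne
  f
}

#' One step of the 1D escape-and-pursuit variant
#'
#' @param state a [swarm_state()] on a ring of length `params$box`.
#' @param params an [ep_params()] object.
#' @return the updated `swarm_state`.
#' @export
step_ep_1d <- function(state, params) {
  N <- state$N; dt <- params$dt
  f <- vapply(seq_len(N), function(i) social_force_1d(state, i, params),
              numeric(1))
  xi <- rnorm(N)
  x <- ring_wrap(state$x + params$v * state$u * dt, params$box)
  u <- state$u + (-params$gamma * state$u + f) * dt +
    sqrt(2 * params$diff * dt) * xi
  swarm_state(x, u, L = params$box, t = state$t + dt, moving = state$moving)
}
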