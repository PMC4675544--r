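#' Swarm state on a periodic ring
#'
#' One time point of a 1D swarm: positions in `[0, L)`, dimensionless
#' velocities, and per-particle motion flags (all `TRUE` for the always-moving
#' alignment models).
#'
#' @param x positions in `[0, L)`.
#' @param u dimensionless velocities, same length as `x`.
#' @param L ring length.
#' @param t time stamp.
#' @param moving logical vector of motion flags; default all `TRUE`.
#' @return an object of class `swarm_state`.
#' @export
swarm_state <- function(x, u, L, t = 0, moving = rep(TRUE, length(x))) {
  N <- length(x)
  if (length(u) != N || length(moving) != N)
    stop("x, u and moving must have equal lengths")
  if (L <= 0) stop("L must be positive")
  if (any(x < 0 | x >= L)) stop("positions must lie in [0, L)")
  structure(list(t = t, x = as.numeric(x), u = as.numeric(u),
                 moving = as.logical(moving), L = L, N = N),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat("<swarm_state> N =", x$N, " L =", format(x$L), " t =", format(x$t),
      " moving:", sum(x$moving), "/", x$N, "\n")
  invisible(x)
}

#' Draw an initial swarm state
#'
#' Positions uniform on the ring and velocities uniform on `[-1, 1]`
#' (positions drawn first, then velocities). All particles start moving.
#' Uses the current R random-number stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param params a `model_params` object.
#' @param phi0 optional target initial order: velocities are drawn uniform on
#'   `[phi0 - spread, phi0 + spread]` instead.
#' @param spread half-width of the velocity draw around `phi0`.
#' @return a `swarm_state`.
#' @export
init_swarm <- function(params, phi0 = NULL, spread = 0.3) {
  N <- params$N
  x <- runif(N, 0, params$L)
  u <- if (is.null(phi0)) runif(N, -1, 1) else runif(N, phi0 - spread, phi0 + spread)
  swarm_state(x, u, L = params$L)
}

#' Two-dimensional swarm state in a periodic box
#'
#' @param pos N x 2 matrix of positions in `[0, box)^2`.
#' @param vel N x 2 matrix of dimensionless velocities.
#' @param box side of the periodic square.
#' @param t time stamp.
#' @return an object of class `swarm_state_2d`.
#' @export
swarm_state_2d <- function(pos, vel, box, t = 0) {
  pos <- as.matrix(pos); vel <- as.matrix(vel)
  if (ncol(pos) != 2 || ncol(vel) != 2 || nrow(pos) != nrow(vel))
    stop("pos and vel must be N x 2 matrices of equal row count")
  if (box <= 0) stop("box must be positive")
  if (any(pos < 0 | pos >= box)) stop("positions must lie in [0, box)")
  structure(list(t = t, pos = pos, vel = vel, box = box, N = nrow(pos)),
            class = "swarm_state_2d")
}

#' Draw an initial 2D state
#'
#' Positions uniform in the box (x-coordinates first, then y), then velocity
#' components from a standard normal scaled by `vel_sd`.
#'
#' @param params an `ep_params` object.
#' @param vel_sd standard deviation of initial velocity components.
#' @return a `swarm_state_2d`.
#' @export
init_swarm_2d <- function(params, vel_sd = 0.5) {
  N <- params$N
  pos <- cbind(runif(N, 0, params$box), runif(N, 0, params$box))
  vel <- matrix(rnorm(2 * N, 0, vel_sd), ncol = 2)
  swarm_state_2d(pos, vel, box = params$box)
}
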