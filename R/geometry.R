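#' Wrap positions onto the periodic ring [0, L)
#'
#' @param x numeric vector of positions.
#' @param L ring length (> 0).
#' @return positions wrapped into `[0, L)`.
#' @export
ring_wrap <- function(x, L) {
  if (L <= 0) stop("ring length L must be positive")
  y <- x - L * floor(x / L)
  y[y >= L] <- y[y >= L] - L
  y
}

#' Minimal-image distance on a periodic ring
#'
#' Distance between two positions on a ring of circumference `L`, taking the
#' shorter of the two arcs. Symmetric in its arguments and never larger than
#' `L / 2`.
#'
#' @param x1,x2 positions in `[0, L)` (vectorised).
#' @param L ring length (> 0).
#' @return non-negative minimal-image distance(s).
#' @examples
#' ring_distance(0.2, 9.9, L = 10) # 0.3, across the seam
#' @export
ring_distance <- function(x1, x2, L) {
  if (L <= 0) stop("ring length L must be positive")
  d <- abs(x1 - x2)
  pmin(d, L - d)
}

#' Minimal-image signed displacement on a ring
#'
#' Signed displacement from `from` to `to` along the shorter arc, in
#' `(-L/2, L/2]`. The sign gives the direction of the shortest path.
#'
#' @param from,to positions in `[0, L)` (vectorised).
#' @param L ring length (> 0).
#' @return signed displacement(s).
#' @export
ring_displacement <- function(from, to, L) {
  if (L <= 0) stop("ring length L must be positive")
  dx <- to - from
  dx - L * round(dx / L)
}

#' Odd alignment response function
#'
#' The piecewise-linear odd function `G(u) = (u + sign(u)) / 2` with
#' `G(0) = 0` used by the alignment models: it pushes a non-zero average
#' direction towards full speed in that direction (`G(1) = 1`, `G(-1) = -1`)
#' while leaving an undecided (zero) average unchanged.
#'
#' @param u numeric vector of dimensionless velocities.
#' @return `G(u)`, same length as `u`.
#' @examples
#' g_function(c(-1, -0.5, 0, 0.5, 1))
#' @export
g_function <- function(u) {
  0.5 * (u + sign(u))
}
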