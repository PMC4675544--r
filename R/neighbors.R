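#' Local average direction around one particle
#'
#' Mean dimensionless velocity over the neighbour set
#' `A_i = { j : ring_distance(x_i, x_j, L) <= delta }`, with or without the
#' focal particle itself, optionally restricted to moving particles. Returns
#' 0 when the qualifying set is empty, the convention used by all the
#' alignment rules.
#'
#' @param state a [swarm_state()].
#' @param i focal particle index (1-based).
#' @param delta interaction range.
#' @param include_self include particle `i` itself in the average?
#' @param moving_only restrict the average to moving particles?
#' @return a scalar local mean velocity.
#' @export
local_mean_u <- function(state, i, delta, include_self = TRUE,
                         moving_only = FALSE) {
  if (i < 1 || i > state$N) stop("index i out of range")
  sel <- ring_distance(state$x[i], state$x, state$L) <= delta
  if (!include_self) sel[i] <- FALSE
  if (moving_only) sel <- sel & state$moving
  if (!any(sel)) return(0)
  mean(state$u[sel])
}

# All-particle neighbour means (vectorised reference used by the R-level step
# functions). Sums run over ascending particle index.
.neighbour_means <- function(x, u, L, delta, include_self = TRUE,
                             moving = NULL) {
  N <- length(x)
  d <- abs(outer(x, x, "-"))
  d <- pmin(d, L - d)
  adj <- d <= delta
  if (!include_self) diag(adj) <- FALSE
  if (!is.null(moving)) adj <- adj & rep(moving, each = N)
  cnt <- rowSums(adj)
  s <- as.vector(adj %*% u)
  ifelse(cnt > 0, s / cnt, 0)
}

# Neighbour index lists (ascending, self excluded).
.neighbour_lists <- function(x, L, delta) {
  N <- length(x)
  d <- abs(outer(x, x, "-"))
  d <- pmin(d, L - d)
  adj <- d <= delta
  diag(adj) <- FALSE
  lapply(seq_len(N), function(i) which(adj[i, ]))
}
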