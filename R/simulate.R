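#' Run a model simulation
#'
#' Simulates one of the marching models for `n_steps` steps from a seeded
#' initial condition, recording the order parameter (and, for pause-and-go,
#' its moving-only variant) every `sample_every` steps. The run is fully
#' deterministic given `(model, params, n_steps, seed)`: the seed initialises
#' one R random-number stream that drives both the initial condition and the
#' dynamics.
#'
#' Model identifiers: `"czirok"` (continuous for `dt < 1`, the discrete model
#' at `dt = 1`), `"individual_choice"`, `"buhl"`, `"bode"`, `"pause_and_go"`,
#' `"escape_pursuit"` (2D) and `"escape_pursuit_1d"`.
#'
#' @param model model identifier string.
#' @param params a parameter object matching the model ([model_params()],
#'   [bode_params()], [png_params()] or [ep_params()]).
#' @param n_steps number of steps (>= 1).
#' @param sample_every record every this many steps (the initial state is
#'   always recorded).
#' @param seed integer seed.
#' @param init optional initial state (a [swarm_state()] or
#'   [swarm_state_2d()]); drawn with [init_swarm()] / [init_swarm_2d()] when
#'   `NULL`.
#' @param store_states also keep full state snapshots (positions, velocities,
#'   motion flags) at the sample times?
#' @return an object of class `swarm_trajectory`: a list with the run
#'   metadata, a `series` data frame (`t`, `phi`, and for pause-and-go
#'   `phi_moving`, `n_moving`), and optionally `states`.
#' @examples
#' traj <- run_simulation("czirok", reference_params(rho = 3.2),
#'                        n_steps = 2000, seed = 1)
#' mean(abs(traj$series$phi))
#' @export
run_simulation <- function(model, params, n_steps, sample_every = 1, seed,
                           init = NULL, store_states = FALSE) {
  models <- c("czirok", "individual_choice", "buhl", "bode", "pause_and_go",
              "escape_pursuit", "escape_pursuit_1d")
  if (!model %in% models)
    stop("unknown model identifier '", model, "'; use one of: ",
         paste(models, collapse = ", "))
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)

  if (model %in% c("czirok", "individual_choice", "buhl")) {
    if (!inherits(params, "model_params")) stop("params must be model_params")
    if (model == "buhl" && params$dt != 1)
      stop("the Buhl update is a discrete-time rule; use dt = 1")
    st <- if (is.null(init)) init_swarm(params) else init
    code <- match(model, c("czirok", "individual_choice", "buhl")) - 1L
    res <- sim_align_cpp(st$x, st$u, params$L, params$v, params$delta,
                         params$dt, params$sigma,
                         params$noise_kind == "uniform",
                         code, params$alpha,
                         params$update_mode == "asynchronous",
                         params$neighbor_mode == "single_random_neighbor",
                         as.integer(n_steps), as.integer(sample_every),
                         store_states)
    series <- data.frame(t = res$t, phi = res$phi)
  } else if (model == "bode") {
    if (!inherits(params, "bode_params")) stop("params must be bode_params")
    st <- if (is.null(init)) init_swarm(params) else init
    res <- sim_bode_cpp(st$x, st$u, params$L, params$v, params$delta,
                        params$r2, params$dt,
                        as.integer(n_steps), as.integer(sample_every),
                        store_states)
    series <- data.frame(t = res$t, phi = res$phi)
  } else if (model == "pause_and_go") {
    if (!inherits(params, "png_params")) stop("params must be png_params")
    st <- if (is.null(init)) init_swarm(params) else init
    res <- sim_png_cpp(st$x, st$u, st$moving, params$L, params$v,
                       params$delta, params$dt, params$sigma,
                       params$noise_kind == "uniform",
                       params$k_walk, params$k_stand0, params$k_stand1,
                       params$n_c_moving, params$a0, params$a1,
                       params$realign_walkers,
                       as.integer(n_steps), as.integer(sample_every),
                       store_states)
    series <- data.frame(t = res$t, phi = res$phi,
                         phi_moving = res$phi_moving, n_moving = res$n_moving)
  } else if (model == "escape_pursuit") {
    if (!inherits(params, "ep_params")) stop("params must be ep_params")
    st <- if (is.null(init)) init_swarm_2d(params) else init
    res <- sim_ep_cpp(st$pos[, 1], st$pos[, 2], st$vel[, 1], st$vel[, 2],
                      params$box, params$v, params$gamma, params$diff,
                      params$chi_e, params$chi_p, params$R, params$dt,
                      as.integer(n_steps), as.integer(sample_every),
                      store_states)
    series <- data.frame(t = res$t, phi_x = res$phi_x, phi_y = res$phi_y)
  } else { # escape_pursuit_1d
    if (!inherits(params, "ep_params")) stop("params must be ep_params")
    st <- if (is.null(init)) {
      x <- runif(params$N, 0, params$box)
      u <- runif(params$N, -1, 1)
      swarm_state(x, u, L = params$box)
    } else init
    res <- sim_ep1d_cpp(st$x, st$u, params$box, params$v, params$gamma,
                        params$diff, params$chi_e, params$chi_p, params$R,
                        params$dt,
                        as.integer(n_steps), as.integer(sample_every),
                        store_states)
    series <- data.frame(t = res$t, phi = res$phi)
  }

  states <- NULL
  if (store_states) {
    if (model == "escape_pursuit")
      states <- list(x = res$x, y = res$y, ux = res$ux, uy = res$uy)
    else if (model == "pause_and_go")
      states <- list(x = res$x, u = res$u, moving = res$moving)
    else
      states <- list(x = res$x, u = res$u,
                     moving = matrix(TRUE, nrow(res$x), ncol(res$x)))
  }
  structure(list(model = model, params = params, seed = seed,
                 n_steps = as.integer(n_steps),
                 sample_every = as.integer(sample_every),
                 series = series, states = states),
            class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat("<swarm_trajectory>", x$model, " N =", x$params$N,
      " steps =", x$n_steps, " seed =", x$seed, "\n")
  cat("  samples:", nrow(x$series),
      " states stored:", !is.null(x$states), "\n")
  invisible(x)
}
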