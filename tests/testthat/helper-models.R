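# Shared fixtures: small parameter sets and run helpers used across tests.

tiny_params <- function(...) {
  model_params(N = 20, L = 10, v = 0.1, eta = 2, delta = 1, dt = 1, ...)
}

# A deterministic state with particles spread evenly and alternating u.
lattice_state <- function(N = 6, L = 10, u = NULL) {
  x <- seq(0, L, length.out = N + 1)[seq_len(N)]
  if (is.null(u)) u <- rep(c(1, -1), length.out = N)
  swarm_state(x, u, L = L)
}

# Iterate an R-level step function n times from a seeded start, returning the
# phi series (used to cross-check the compiled loop).
iterate_steps <- function(step_fun, state, params, n) {
  phis <- numeric(n + 1)
  phis[1] <- mean(state$u)
  for (k in seq_len(n)) {
    state <- step_fun(state, params)
    phis[k + 1] <- mean(state$u)
  }
  list(state = state, phi = phis)
}
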