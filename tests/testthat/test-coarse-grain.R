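mk_series <- function(phi, dt = 1) order_series(seq_along(phi) * dt - dt, phi)

test_that("order_parameter extracts phi and the moving-only variant", {
  p <- model_params(N = 2, L = 10, eta = 0, dt = 1)
  st <- swarm_state(c(1, 2), c(1, -1), L = 10)
  tr <- run_simulation("czirok", p, n_steps = 2, seed = 1, init = st)
  expect_equal(order_parameter(tr)$phi[1], 0)
  st2 <- swarm_state(c(1, 2), c(1, 1), L = 10)
  tr2 <- run_simulation("czirok", p, n_steps = 2, seed = 1, init = st2)
  expect_equal(order_parameter(tr2)$phi[1], 1)
  # moving-only: one mover with u = 0.8 among standers
  pp <- png_params(N = 10, L = 20, k_walk = 0, k_stand0 = 0, k_stand1 = 0)
  stm <- swarm_state(seq(0, 18, by = 2), c(0.8, rep(-1, 9)), L = 20,
                     moving = c(TRUE, rep(FALSE, 9)))
  trm <- run_simulation("pause_and_go", pp, n_steps = 2, seed = 1, init = stm)
  sm <- order_parameter(trm, moving_only = TRUE)
  expect_equal(sm$phi[1], 0.8)
  expect_false(sm$undefined[1])
})

test_that("mean_order takes |phi| after burn-in", {
  expect_equal(mean_order(mk_series(rep(-0.9, 100))), 0.9)
  expect_equal(mean_order(mk_series(rep(c(0.4, -0.4), 50))), 0.4)
  s <- mk_series(c(rep(0, 50), rep(1, 50)))
  expect_equal(mean_order(s, burn_in = 50), 1)
  expect_error(mean_order(mk_series(c(0, 1)), burn_in = 10), "burn_in")
})

test_that("transitions applies the hysteresis rule for switch counting", {
  expect_equal(transitions(mk_series(c(0.9, 0.9, -0.9)), 0.7)$n_switches, 1L)
  expect_equal(transitions(mk_series(c(0.5, -0.6, 0.3, 0.69)), 0.7)$n_switches, 0L)
  expect_equal(transitions(mk_series(c(0.9, 0.3, 0.9)), 0.7)$n_switches, 0L)
  expect_equal(transitions(mk_series(c(0.9, 0.3, -0.9, 0.1, -0.8, 0.9)), 0.7)$n_switches, 2L)
  tr <- transitions(mk_series(c(0.8, 0, -0.8, 0, 0.8)), 0.7)
  expect_equal(tr$waits, c(2, 2))
  expect_equal(tr$rate, 2 / 4)
  expect_equal(as.character(tr$labels),
               c("A+", "D", "A-", "D", "A+"))
  expect_error(transitions(mk_series(c(0, 1)), 1.2), "p must be")
})

test_that("transitions is invariant under phi -> -phi", {
  set.seed(71)
  phi <- cumsum(rnorm(4000, 0, 0.1)); phi <- phi / max(abs(phi)) * 1.1
  a <- transitions(mk_series(phi), 0.7)
  b <- transitions(mk_series(-phi), 0.7)
  expect_identical(a$n_switches, b$n_switches)
  expect_identical(a$waits, b$waits)
  swap <- c("A+" = "A-", "A-" = "A+", "D" = "D")
  expect_identical(unname(swap[as.character(a$labels)]),
                   as.character(b$labels))
})

test_that("exponential waiting-time fit recovers the rate", {
  f <- fit_exponential_waits(rep(2.5, 10))
  expect_equal(f$rate, 0.4)
  set.seed(72)
  w <- rexp(1e4, rate = 2)
  f2 <- fit_exponential_waits(w)
  expect_lt(abs(f2$rate - 2), 3 * 2 / sqrt(1e4))
  expect_gt(f2$p_value, 0.01)
  expect_error(fit_exponential_waits(3), "at least 2")
})

test_that("estimate_FD: pure drift gives constant F and zero D", {
  phi <- seq(-1, 1, by = 0.002) # phi_{t+1} = phi_t + 0.002
  s <- mk_series(phi)
  est <- estimate_FD(s, dt_cg = 1, n_bins = 11, min_count = 20)
  expect_true(any(est$valid))
  expect_equal(est$F[est$valid], rep(0.002, sum(est$valid)), tolerance = 1e-12)
  expect_equal(est$D[est$valid], rep(0, sum(est$valid)), tolerance = 1e-15)
  expect_error(estimate_FD(s, dt_cg = 1.5), "integer multiple")
  # min_count masks sparse bins
  expect_true(all(est$count[!est$valid] < 20))
})

test_that("estimate_FD recovers OU drift and diffusion within 10%", {
  s <- synth_sde(drift_ou(1), diffusion_const(0.1), T = 1e4, dt = 0.01,
                 seed = 73, sample_every = 5)
  est <- estimate_FD(s, dt_cg = 0.05, n_bins = 31, min_count = 500,
                     phi_range = c(-1.2, 1.2))
  v <- est$valid
  slope <- coef(lm(est$F[v] ~ est$bin_center[v]))[2]
  expect_lt(abs(slope - (-1)), 0.1)
  expect_lt(abs(mean(est$D[v]) - 0.1), 0.01)
})

test_that("double-well drift yields stable/unstable/stable fixed points", {
  s <- synth_sde(drift_double_well(1, 1), diffusion_const(0.1), T = 5e3,
                 dt = 0.01, seed = 74, sample_every = 5)
  est <- estimate_FD(s, dt_cg = 0.05, n_bins = 25, min_count = 200)
  fp <- classify_fixed_points(est)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
  expect_lt(max(abs(fp$location - c(-1, 0, 1))), 0.15)
  # F has no fixed point when it never changes sign
  est_pos <- est
  est_pos$F <- abs(est_pos$F) + 0.01
  expect_equal(nrow(classify_fixed_points(est_pos)), 0L)
})

test_that("estimator error shrinks with trajectory length", {
  err <- sapply(c(2e3, 8e3), function(T) {
    s <- synth_sde(drift_ou(1), diffusion_const(0.1), T = T, dt = 0.01,
                   seed = 75, sample_every = 5)
    est <- estimate_FD(s, dt_cg = 0.05, n_bins = 21, min_count = 200)
    v <- est$valid & abs(est$bin_center) < 0.8
    mean(abs(est$F[v] - (-est$bin_center[v])))
  })
  expect_lt(err[2], 0.75 * err[1]) # ~ halves when T quadruples
})

test_that("variance and second-moment D estimates diverge as dt_cg grows", {
  s <- synth_sde(drift_double_well(1, 1), diffusion_const(0.1), T = 4e3,
                 dt = 0.01, seed = 76, sample_every = 5)
  div <- sapply(c(0.05, 0.25, 1), function(dtcg) {
    ev <- estimate_FD(s, dt_cg = dtcg, n_bins = 15, min_count = 100,
                      method = "variance")
    e2 <- estimate_FD(s, dt_cg = dtcg, n_bins = 15, min_count = 100,
                      method = "second_moment")
    v <- ev$valid & e2$valid
    mean(abs(e2$D[v] - ev$D[v]))
  })
  expect_true(all(diff(div) > 0))
  # the gap is F^2 dt_cg / 2 per bin, so it vanishes as dt_cg -> 0
  expect_lt(div[1], 0.005)
})

test_that("single-long and many-short sampling agree at small dt_cg", {
  long <- synth_sde(drift_ou(1), diffusion_const(0.1), T = 2e3, dt = 0.01,
                    seed = 77, sample_every = 2)
  shorts <- lapply(1:400, function(k) {
    synth_sde(drift_ou(1), diffusion_const(0.1), T = 4, dt = 0.01,
              seed = 1e5 + k, phi0 = runif(1, -0.9, 0.9), sample_every = 2)
  })
  el <- estimate_FD(long, dt_cg = 0.02, n_bins = 15, min_count = 300)
  es <- estimate_FD(shorts, dt_cg = 0.02, n_bins = 15, min_count = 300)
  v <- el$valid & es$valid
  expect_gt(sum(v), 5)
  expect_lt(abs(mean(es$D[v]) - mean(el$D[v])) / mean(el$D[v]), 0.15)
})

test_that("synth_sde honours its specs and is reproducible across paths", {
  s0 <- synth_sde(drift_zero(), diffusion_const(0), T = 10, dt = 0.1, seed = 1,
                  phi0 = 0.3)
  expect_equal(s0$phi, rep(0.3, 101))
  s1 <- synth_sde(drift_zero(), diffusion_const(0.05), T = 500, dt = 0.1,
                  seed = 2)
  expect_lt(abs(mean(diff(s1$phi))), 3 * sd(diff(s1$phi)) / sqrt(5000))
  # OU stationary variance D0 / theta
  s2 <- synth_sde(drift_ou(2), diffusion_const(0.1), T = 2000, dt = 0.01,
                  seed = 3, sample_every = 10)
  expect_lt(abs(var(s2$phi[-(1:500)]) - 0.05), 0.008)
  # descriptor route (compiled) and R-function route draw the same stream
  sc <- synth_sde(drift_ou(1), diffusion_const(0.1), T = 50, dt = 0.01, seed = 4)
  sf <- synth_sde(function(x) -x, function(x) 0.1, T = 50, dt = 0.01, seed = 4)
  expect_equal(sf$phi, sc$phi, tolerance = 1e-12)
})

test_that("undefined samples are excluded from increments", {
  phi <- c(0.1, 0.2, 5, 0.3, 0.4, 0.5)
  s <- order_series(0:5, phi, n_moving = c(3, 3, 0, 3, 3, 3),
                    undefined = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  est <- estimate_FD(s, dt_cg = 1, n_bins = 5, min_count = 1,
                     phi_range = c(0, 1))
  # increments touching the flagged sample are dropped: only 3 remain
  expect_equal(sum(est$count), 3)
})
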