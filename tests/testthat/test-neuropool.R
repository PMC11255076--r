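test_that("steady states of the pool ODEs match the closed-form limits", {
  # zero drive, zero state stays at rest
  p0 <- pool_params(t1 = 1, t2 = 1, C11 = 1, C12 = 1, C21 = 1, C22 = 0,
                    D = 0)
  traj <- simulate_pools(p0, duration = 5, dt = 0.01)
  expect_equal(max(abs(traj$I1)), 0)
  expect_equal(max(abs(traj$I2)), 0)

  # K = 1 unit case: both pools settle at 1
  p1 <- pool_params(t1 = 1, t2 = 1, C11 = 1, C12 = 1, C21 = 1, C22 = 0,
                    D = 1)
  expect_equal(unname(pool_steady_state(p1)), c(1, 1))
  traj1 <- simulate_pools(p1, duration = 40, dt = 0.01)
  expect_equal(tail(traj1$I1, 1), 1, tolerance = 1e-6)
  expect_equal(tail(traj1$I2, 1), 1, tolerance = 1e-6)

  # asymmetric case: I1 limit = D(1+C22)/K = 6
  p2 <- pool_params(t1 = 2, t2 = 1, C11 = 1.5, C12 = 2, C21 = 1, C22 = 1,
                    D = 3)
  expect_equal(unname(pool_steady_state(p2)[1]), 6)
  traj2 <- simulate_pools(p2, duration = 80, dt = 0.01)
  expect_equal(tail(traj2$I1, 1), 6, tolerance = 1e-5)
})

test_that("pool parameter validation and instability are reported", {
  expect_error(pool_params(t1 = -1, t2 = 1, C11 = 1, C12 = 1, C21 = 1,
                           C22 = 0), "positive")
  # K = 0 boundary: C21*C12 = (C11-1)(1+C22)
  pk0 <- pool_params(t1 = 1, t2 = 1, C11 = 2, C12 = 1, C21 = 1, C22 = 0,
                     D = 1)
  expect_equal(stability_k(pk0), 0)
  expect_error(to_canonical(pk0), "no oscillator")
  expect_error(pool_steady_state(pk0), "unstable")
  expect_warning(simulate_pools(pk0, duration = 1, dt = 0.01), "unstable")
})

test_that("canonical conversion reproduces hand-derived parameters", {
  c1 <- to_canonical(pool_params(t1 = 1, t2 = 1, C11 = 1, C12 = 1, C21 = 1,
                                 C22 = 0, D = 1))
  expect_equal(c1$wn, 1)
  expect_equal(c1$zeta, 0.5)
  expect_equal(c1$A, 1)
  expect_equal(c1$B, 1)

  c2 <- to_canonical(pool_params(t1 = 2, t2 = 1, C11 = 1.5, C12 = 2,
                                 C21 = 1, C22 = 1, D = 3))
  expect_equal(c2$wn, sqrt(0.5))
  expect_equal(c2$zeta, 3.5 / (2 * sqrt(0.5) * 2), tolerance = 1e-12)
  expect_equal(c2$A, 3)
  expect_equal(c2$B, 6)
})

test_that("canonical (wn, zeta) match the eigenvalues of the system matrix", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_stable_pool()
    cp <- to_canonical(p)
    expect_equal(canon_pair(cp), eig_pair(pool_matrix(p)),
                 tolerance = 1e-8)
  }
})

test_that("closed-form step response agrees with ODE integration", {
  set.seed(7)
  times <- seq(0, 60, by = 0.25)
  for (i in 1:20) {
    p <- random_stable_pool()
    cp <- to_canonical(p)
    traj <- simulate_pools(p, duration = 60, dt = 0.01)
    idx <- match(times, traj$t)
    closed <- step_response(cp, times)
    scale <- max(abs(cp$B), 1)
    expect_lt(max(abs(closed - traj$I1[idx])) / scale, 1e-4)
    # simulated asymptote equals the steady-state step amplitude B
    expect_equal(tail(traj$I1, 1), cp$B, tolerance = 2e-3 * scale)
  }
})

test_that("halving the integration step changes trajectories below 1e-6", {
  p <- pool_params(t1 = 2, t2 = 1, C11 = 1.5, C12 = 2, C21 = 1, C22 = 1,
                   D = 3)
  a <- simulate_pools(p, duration = 10, dt = 0.01)
  b <- simulate_pools(p, duration = 10, dt = 0.005)
  idx <- match(a$t, b$t)
  expect_lt(max(abs(a$I1 - b$I1[idx])), 1e-6)
})

test_that("step response handles damping regimes, delay and the A term", {
  # DC values: asymptote = baseline + B regardless of A
  fig6 <- canonical_params(wn = 0.375, zeta = 0.7, A = 0, B = 9,
                           baseline = 7.6, onset_delay = 2)
  expect_equal(step_response(fig6, 1e5), 16.6)
  expect_equal(dc_gain(fig6), 9)
  fig2 <- canonical_params(wn = 0.075, zeta = 0.7, A = 0, B = 18.5,
                           time_unit = "s")
  expect_equal(step_response(fig2, 1e5), 18.5)
  expect_equal(dc_gain(fig2), 18.5)
  expect_equal(dc_gain(canonical_params(wn = 1, zeta = 1, A = 5, B = 0)), 0)

  # response equals baseline before the onset delay
  expect_equal(step_response(fig6, c(0, 1, 1.99)), rep(7.6, 3))

  # peak overshoot fraction for zeta = 0.7 is exp(-pi*zeta/sqrt(1-zeta^2))
  cp <- canonical_params(wn = 1, zeta = 0.7, A = 0, B = 1)
  y <- step_response(cp, seq(0, 30, by = 1e-3))
  expect_equal(max(y) - 1, exp(-pi * 0.7 / sqrt(1 - 0.7^2)),
               tolerance = 1e-5)

  # monotone settling for zeta >= 1 (A = 0, B > 0)
  set.seed(11)
  for (i in 1:5) {
    cp <- canonical_params(wn = runif(1, 0.2, 2), zeta = runif(1, 1, 2),
                           A = 0, B = runif(1, 1, 10))
    y <- step_response(cp, seq(0, 50, by = 0.05))
    expect_gte(min(diff(y)), -1e-12)
  }

  # critically damped form continuous with the neighboring regimes
  t_eval <- seq(0, 10, by = 0.1)
  y1 <- step_response(canonical_params(wn = 1, zeta = 1, A = 2, B = 3),
                      t_eval)
  y2 <- step_response(canonical_params(wn = 1, zeta = 1 + 1e-7, A = 2,
                                       B = 3), t_eval)
  expect_equal(y1, y2, tolerance = 1e-5)

  expect_error(canonical_params(wn = -1, zeta = 0.7, B = 1), "wn")
  expect_error(canonical_params(wn = 1, zeta = 0, B = 1), "zeta")
  expect_error(step_response(fig6, c(2, 1)), "non-decreasing")
})
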