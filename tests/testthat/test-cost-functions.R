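stationary_traj <- function(par, q = c(0.4, 1.2), T = 0.5, n = 101) {
  t <- seq(0, T, length.out = n)
  z <- matrix(0, n, 2)
  reach_trajectory(t, matrix(q, n, 2, byrow = TRUE), z, z, z, par,
                   u = z)
}

test_that("rest is cost-free except for the gravity-holding torque", {
  par <- fx_params()
  q <- c(0.4, 1.2); T <- 0.5
  tr <- stationary_traj(par, q, T)
  cb <- all_basis_costs(tr, par, eps = 0)
  expect_equal(unname(cb[c("hand_jerk", "angle_jerk", "angle_accel",
                           "torque_change", "geodesic", "energy",
                           "effort")]),
               rep(0, 7), tolerance = 1e-12)
  expect_equal(unname(cb["torque"]), T * sum(gravity_torque(q, par)^2),
               tolerance = 1e-10)
})

test_that("hand-jerk cost of the analytic quintic matches the closed form", {
  par <- fx_params()
  p0 <- c(0.30, 0.10); pf <- c(0.58, 0.28); T <- 0.64
  mj <- min_jerk_analytic(p0, pf, T, 401, par)
  D2 <- sum((pf - p0)^2)
  expect_equal(evaluate_basis_cost(mj, "hand_jerk", par),
               720 * D2 / T^5, tolerance = 5e-3)
})

test_that("all eight costs are invariant under time reversal (B = 0)", {
  par <- arm_params(B = matrix(0, 2, 2))
  tr <- fx_curved_traj(par)
  n <- length(tr$t)
  rev_idx <- n:1
  tr_rev <- reach_trajectory(tr$t, tr$q[rev_idx, ], -tr$qd[rev_idx, ],
                             tr$qdd[rev_idx, ], -tr$qddd[rev_idx, ], par)
  cb <- all_basis_costs(tr, par, eps = 0)
  cb_rev <- all_basis_costs(tr_rev, par, eps = 0)
  # u is finite-differenced, so the effort term carries small edge error
  expect_equal(cb[1:7], cb_rev[1:7], tolerance = 1e-8)
  expect_equal(cb[8], cb_rev[8], tolerance = 1e-3)
})

test_that("composite cost is linear and degree-1 homogeneous in alpha", {
  par <- fx_params()
  tr <- fx_curved_traj(par)
  s <- rep(1, 8)
  w1 <- cost_weights(c(angle_accel = 1), s)
  expect_equal(composite_cost(tr, w1, par),
               evaluate_basis_cost(tr, "angle_accel", par))
  set.seed(5)
  a <- runif(8, 0.1, 2)
  expect_equal(composite_cost(tr, cost_weights(2 * a, s), par),
               2 * composite_cost(tr, cost_weights(a, s), par),
               tolerance = 1e-12)
  expect_equal(composite_cost(tr, cost_weights(a, s), par),
               sum(a * all_basis_costs(tr, par)), tolerance = 1e-12)
  expect_error(cost_weights(rep(0, 8)), "at least one")
  expect_error(cost_weights(c(hand_jerk = -1, torque = 1)), "non-negative")
})

test_that("cost contributions are normalized fractions", {
  par <- fx_params()
  tr <- fx_curved_traj(par)
  w1 <- cost_weights(c(torque = 3))
  expect_equal(unname(cost_contributions(tr, w1, par)["torque"]), 1)
  set.seed(9)
  for (i in 1:5) {
    w <- cost_weights(runif(8, 0.01, 1))
    fr <- cost_contributions(tr, w, par)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_true(all(fr >= 0))
  }
  tr0 <- stationary_traj(par)
  expect_error(cost_contributions(tr0, cost_weights(c(hand_jerk = 1)), par),
               "zero")
})

test_that("absolute work converges monotonically from above as eps -> 0", {
  par <- fx_params()
  tr <- fx_curved_traj(par)
  eps <- 10^seq(-1, -7, by = -1)
  vals <- sapply(eps, function(e) evaluate_basis_cost(tr, "energy", par, e))
  expect_true(all(diff(vals) < 0))
  exact <- sum(tr$quad_w * rowSums(abs(tr$tau * tr$qd)))
  expect_gt(min(vals), exact - 1e-12)
  expect_equal(vals[length(vals)], exact, tolerance = 1e-6)
})

test_that("costs are grid-converged beyond 200 samples", {
  par <- fx_params()
  for (n in c(401)) {
    c200 <- all_basis_costs(fx_curved_traj(par, n = 201), par)
    cn <- all_basis_costs(fx_curved_traj(par, n = n), par)
    expect_lt(max(abs(cn - c200) / pmax(abs(cn), 1e-12)), 1e-3)
  }
})

test_that("basis-cost ids resolve by name and index, unknown ids error", {
  par <- fx_params()
  tr <- fx_curved_traj(par)
  for (i in 1:8)
    expect_equal(evaluate_basis_cost(tr, i, par),
                 evaluate_basis_cost(tr, cost_names()[i], par))
  expect_error(evaluate_basis_cost(tr, "speed", par), "unknown")
})
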