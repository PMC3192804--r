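test_that("forward kinematics places the fully extended arm on the axes", {
  par <- arm_params(l1 = 0.30, l2 = 0.35)
  expect_equal(drop(forward_kinematics(c(0, 0), par)$p), c(0.65, 0),
               tolerance = 1e-12)
  expect_equal(drop(forward_kinematics(c(pi / 2, 0), par)$p), c(0, 0.65),
               tolerance = 1e-12)
})

test_that("inverse kinematics round-trips over the reachable annulus", {
  par <- fx_params()
  set.seed(42)
  for (i in 1:100) {
    r <- runif(1, abs(par$l1 - par$l2) + 1e-3, par$L - 1e-3)
    th <- runif(1, -pi, pi)
    p <- r * c(cos(th), sin(th))
    q <- inverse_kinematics(p, par)
    expect_true(q[2] >= 0 && q[2] <= pi)  # default elbow branch
    expect_lt(max(abs(drop(forward_kinematics(q, par)$p) - p)), 1e-10)
  }
  # mirror branch round-trips too, with negated elbow angle
  p <- c(0.30, -0.35)
  qd <- inverse_kinematics(p, arm_params(l1 = 0.30, l2 = 0.35),
                           branch = "down")
  expect_lt(qd[2], 0)
  expect_lt(max(abs(drop(forward_kinematics(
    qd, arm_params(l1 = 0.30, l2 = 0.35))$p) - p)), 1e-10)
})

test_that("unreachable points raise a domain error naming the bound", {
  par <- fx_params()
  expect_error(inverse_kinematics(c(par$L + 0.1, 0), par), "beyond reach")
  expect_error(inverse_kinematics(c(0.01, 0), par), "annulus")
})

test_that("inverse dynamics: gravity compensation and inertia columns", {
  par <- fx_params()
  q <- c(0.4, 1.1)
  expect_equal(drop(inverse_dynamics(q, c(0, 0), c(0, 0), par)),
               drop(gravity_torque(q, par)), tolerance = 1e-12)
  par0 <- arm_params(g = 0)
  M <- inertia_matrix(q, par0)
  expect_equal(drop(inverse_dynamics(q, c(0, 0), c(1, 0), par0)), M[, 1],
               tolerance = 1e-12)
  expect_equal(drop(inverse_dynamics(q, c(0, 0), c(0, 1), par0)), M[, 2],
               tolerance = 1e-12)
})

test_that("inverse dynamics is the algebraic inverse of the forward model", {
  par <- fx_params()
  set.seed(7)
  for (i in 1:20) {
    q <- c(runif(1, -1, 2), runif(1, 0.1, 2.5))
    qd <- runif(2, -3, 3)
    tau <- runif(2, -10, 10)
    rhs <- dynamics_rhs(list(q = q, qdot = qd, tau = tau,
                             taudot = c(0, 0)), c(0, 0), par)
    expect_lt(max(abs(inverse_dynamics(q, qd, rhs$qddot, par) - tau)), 1e-10)
  }
  expect_error(dynamics_rhs(list(q = c(NaN, 0), qdot = c(0, 0),
                                 tau = c(0, 0), taudot = c(0, 0)),
                            c(0, 0), par), "non-finite")
})

test_that("static equilibrium is a fixed point of the dynamics", {
  par <- fx_params()
  q <- c(0.3, 0.9)
  rhs <- dynamics_rhs(list(q = q, qdot = c(0, 0),
                           tau = drop(gravity_torque(q, par)),
                           taudot = c(0, 0)), c(0, 0), par)
  expect_equal(rhs$qddot, c(0, 0), tolerance = 1e-12)
  expect_equal(rhs$qdot, c(0, 0))
})

test_that("inertia matrix is symmetric positive definite everywhere", {
  par <- fx_params()
  set.seed(1)
  ev <- replicate(1000, {
    M <- inertia_matrix(c(runif(1, -pi, pi), runif(1, -pi, pi)), par)
    expect_equal(M[1, 2], M[2, 1])
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_gt(min(ev), 0)
})

test_that("Mdot - 2C is skew-symmetric (passivity)", {
  par <- fx_params()
  co <- reachioc:::.dyn_coefs(par)
  set.seed(2)
  for (i in 1:50) {
    q2 <- runif(1, -pi, pi)
    qd <- runif(2, -5, 5)
    s2 <- sin(q2)
    Mdot <- -co$a2 * s2 * qd[2] * matrix(c(2, 1, 1, 0), 2, 2)
    C <- co$a2 * s2 * matrix(c(-qd[2], qd[1], -(qd[1] + qd[2]), 0), 2, 2)
    S <- Mdot - 2 * C
    expect_lt(max(abs(S + t(S))), 1e-10)
  }
})

test_that("shoulder-only arm reduces to a gravity pendulum", {
  tiny <- 1e-9
  par <- arm_params(m2 = tiny, I2 = tiny, lc2 = tiny,
                    B = matrix(0, 2, 2))
  period <- 2 * pi * sqrt((par$I1 + par$m1 * par$lc1^2) /
                            (par$m1 * par$g * par$lc1))
  # integrate small oscillations about the hanging equilibrium q1 = -pi/2
  amp <- 0.02
  state <- c(-pi / 2 + amp, 0, 0, 0)
  h <- period / 4000
  f <- function(st) {
    r <- dynamics_rhs(list(q = c(st[1], st[2]), qdot = c(st[3], st[4]),
                           tau = c(0, 0), taudot = c(0, 0)), c(0, 0), par)
    c(st[3], st[4], r$qddot)
  }
  n <- 8000
  traj <- numeric(n)
  st <- state
  for (i in seq_len(n)) {  # RK4
    k1 <- f(st); k2 <- f(st + h / 2 * k1)
    k3 <- f(st + h / 2 * k2); k4 <- f(st + h * k3)
    st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    traj[i] <- st[1] + pi / 2
  }
  # period from successive downward zero crossings
  cross <- which(diff(sign(traj)) < 0)
  measured <- h * mean(diff(cross))
  expect_lt(abs(measured - period) / period, 0.005)
})

test_that("energy balance holds along frictionless motion", {
  par <- arm_params(B = matrix(0, 2, 2))
  tr <- fx_curved_traj(par)
  E <- reachioc:::.mechanical_energy(tr$q, tr$qd, par)
  dE <- reachioc:::fd_derivative(tr$t, matrix(E, ncol = 1))
  pow <- rowSums(tr$tau * tr$qd)
  i <- 10:(length(E) - 10)
  expect_lt(max(abs(dE[i] - pow[i])), 1e-3 * max(abs(pow)))
})

test_that("torque_rate matches numerical differentiation of torques", {
  par <- fx_params()
  tr <- fx_curved_traj(par)
  taud_fd <- reachioc:::fd_derivative(tr$t, tr$tau)
  i <- 5:(nrow(tr$tau) - 5)
  expect_lt(max(abs(tr$taud[i, ] - taud_fd[i, ])),
            1e-3 * max(abs(tr$taud)))
})
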