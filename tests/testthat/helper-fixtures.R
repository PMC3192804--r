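# Shared fixtures, memoized across test files (one R session per test run).
# Everything is generated in code; solver-based fixtures are computed once.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_params <- function() fx_get("params", function() arm_params())

fx_opts <- function() fx_get("opts", function()
  solver_options(nodes = 24, maxit = 200))

# two mid-range postures, enough for inversion tests
fx_tasks <- function() fx_get("tasks", function()
  default_postures(fx_params())[c("P2", "P3")])

# single-cost optimal values on the two point-to-point versions of the
# tasks, plus the derived re-scaling vector
fx_single_cost <- function() fx_get("single_cost", function() {
  par <- fx_params()
  opts <- fx_opts()
  pt_tasks <- lapply(fx_tasks(), function(tk) {
    p0 <- forward_kinematics(tk$q0, par)$p
    task_spec(tk$q0, point_target(c(tk$target$d, p0[2])), tk$T, tk$label)
  })
  vals <- sapply(pt_tasks, function(tk) {
    sapply(cost_names(), function(cn)
      solve_ocp(tk, cost_weights(stats::setNames(1, cn)), par,
                opts)$basis_costs[[cn]])
  })
  list(values = vals, s = 1 / apply(vals, 1, stats::median))
})

fx_rescaling <- function() fx_single_cost()$s

# noise-free observation set generated from the pure angle-acceleration cost
fx_obs_accel <- function() fx_get("obs_accel", function() {
  s <- fx_rescaling()
  generate_observations(cost_weights(c(angle_accel = 1), s), fx_tasks(),
                        noise_model(0, 0, 0, 0, seed = 11), n_trials = 2,
                        params = fx_params(), options = fx_opts())
})

# a generic smooth curved trajectory (arc-like hand path) for cost tests
fx_curved_traj <- function(params = fx_params(), n = 201, T = 0.7) {
  s <- seq(0, 1, length.out = n)
  sg <- 10 * s^3 - 15 * s^4 + 6 * s^5
  sg1 <- (30 * s^2 - 60 * s^3 + 30 * s^4) / T
  sg2 <- (60 * s - 180 * s^2 + 120 * s^3) / T^2
  sg3 <- (60 - 360 * s + 360 * s^2) / T^3
  th0 <- -0.3; th1 <- 0.55; r <- 0.55 * params$L
  th <- th0 + (th1 - th0) * sg
  p <- r * cbind(cos(th), sin(th))
  dth <- th1 - th0
  v <- r * cbind(-sin(th), cos(th)) * (dth * sg1)
  a <- r * (cbind(-sin(th), cos(th)) * (dth * sg2) -
              cbind(cos(th), sin(th)) * (dth * sg1)^2)
  j <- r * (cbind(-sin(th), cos(th)) * (dth * sg3) -
              3 * cbind(cos(th), sin(th)) * (dth^2 * sg1 * sg2) +
              cbind(sin(th), -cos(th)) * (dth * sg1)^3)
  reachioc:::.traj_from_hand_analytic(s * T, p, v, a, j, params)
}

# shoelace polygon area (independent oracle for the Monte-Carlo estimate)
shoelace_area <- function(poly) {
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2])) / 2
}

# random star-shaped (hence simple) polygon around a centre
random_star_polygon <- function(nv = 12) {
  th <- sort(stats::runif(nv, 0, 2 * pi))
  r <- stats::runif(nv, 0.3, 1)
  cbind(r * cos(th), r * sin(th))
}
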