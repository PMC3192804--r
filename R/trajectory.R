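#' @keywords internal
# Derivative of sampled data on a (possibly non-uniform) grid, using
# three-point stencils in the interior and one-sided stencils at the ends.
fd_derivative <- function(t, y) {
  y <- .as_qmat(y)
  n <- length(t)
  stopifnot(n >= 3, nrow(y) == n)
  out <- matrix(0, n, ncol(y))
  i <- 2:(n - 1)
  h1 <- t[i] - t[i - 1]
  h2 <- t[i + 1] - t[i]
  for (j in seq_len(ncol(y))) {
    out[i, j] <- (-h2 / (h1 * (h1 + h2))) * y[i - 1, j] +
      ((h2 - h1) / (h1 * h2)) * y[i, j] +
      (h1 / (h2 * (h1 + h2))) * y[i + 1, j]
    # quadratic one-sided stencils at the boundaries
    h1a <- t[2] - t[1]; h2a <- t[3] - t[2]
    out[1, j] <- (-(2 * h1a + h2a) / (h1a * (h1a + h2a))) * y[1, j] +
      ((h1a + h2a) / (h1a * h2a)) * y[2, j] -
      (h1a / (h2a * (h1a + h2a))) * y[3, j]
    h1b <- t[n - 1] - t[n - 2]; h2b <- t[n] - t[n - 1]
    out[n, j] <- (h2b / (h1b * (h1b + h2b))) * y[n - 2, j] -
      ((h1b + h2b) / (h1b * h2b)) * y[n - 1, j] +
      ((h1b + 2 * h2b) / (h2b * (h1b + h2b))) * y[n, j]
  }
  out
}

# Trapezoidal quadrature weights for a (non-uniform) grid.
.trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

#' Reaching trajectory container
#'
#' Assembles the full state along a joint motion: joint kinematics up to
#' jerk, torques and torque rates (by inverse dynamics, exactly), the motor
#' command `u = tau-double-dot`, and the fingertip kinematics up to jerk
#' (forward kinematics by the chain rule). Every cost functional and every
#' movement metric in the package consumes this object.
#'
#' @param t strictly increasing time grid (s).
#' @param q joint angles, n x 2 matrix.
#' @param qd,qdd,qddd joint velocity / acceleration / jerk; computed by
#'   finite differencing of `q` when missing (intended for measured data —
#'   solver output always supplies exact derivatives).
#' @param params an [arm_params()] object.
#' @param u optional motor command samples; differenced from the analytic
#'   torque rate when missing.
#' @param quad_w optional quadrature weights matched to the grid (defaults
#'   to trapezoidal weights).
#' @return an object of class `reach_trajectory`.
#' @export
reach_trajectory <- function(t, q, qd = NULL, qdd = NULL, qddd = NULL,
                             params, u = NULL, quad_w = NULL) {
  q <- .as_qmat(q)
  n <- length(t)
  stopifnot(n == nrow(q), all(diff(t) > 0), all(is.finite(q)))
  if (is.null(qd)) qd <- fd_derivative(t, q)
  if (is.null(qdd)) qdd <- fd_derivative(t, qd)
  if (is.null(qddd)) qddd <- fd_derivative(t, qdd)
  qd <- .as_qmat(qd); qdd <- .as_qmat(qdd); qddd <- .as_qmat(qddd)
  tau <- .as_qmat(inverse_dynamics(q, qd, qdd, params))
  taud <- .as_qmat(torque_rate(q, qd, qdd, qddd, params))
  if (is.null(u)) u <- fd_derivative(t, taud)
  hand <- forward_kinematics(q, params, qd, qdd, qddd)
  structure(list(t = t, q = q, qd = qd, qdd = qdd, qddd = qddd,
                 tau = tau, taud = taud, u = .as_qmat(u),
                 hand = hand, T = t[n] - t[1],
                 quad_w = if (is.null(quad_w)) .trapz_weights(t) else quad_w),
            class = "reach_trajectory")
}

#' Build a trajectory from a fingertip path
#'
#' Converts a sampled fingertip path to joint space via inverse kinematics
#' and differentiates the joint series with smoothing-free cubic splines.
#' Used to turn hand-level constructions (analytic profiles, measured paths)
#' into full-state trajectories.
#'
#' @param t time grid (s).
#' @param p fingertip positions, n x 2 (x, z).
#' @param params an [arm_params()] object.
#' @param branch elbow branch for [inverse_kinematics()].
#' @return a `reach_trajectory`.
#' @export
trajectory_from_hand <- function(t, p, params, branch = "up") {
  q <- .as_qmat(inverse_kinematics(p, params, branch))
  sd1 <- apply(q, 2, function(y) stats::splinefun(t, y))
  dmat <- function(deriv) sapply(sd1, function(f) f(t, deriv = deriv))
  reach_trajectory(t, q, dmat(1), dmat(2), dmat(3), params)
}

#' Tangential fingertip speed of a trajectory
#' @param traj a `reach_trajectory`.
#' @return numeric vector of speeds (m/s).
#' @export
hand_speed <- function(traj) sqrt(rowSums(traj$hand$v^2))

#' Resample a trajectory on a time-normalized uniform grid
#'
#' @param traj a `reach_trajectory`.
#' @param n number of output samples.
#' @param params an [arm_params()] object (defaults to the one implied by
#'   the stored fields; must be passed since trajectories do not retain it).
#' @return a `reach_trajectory` on `n` uniformly spaced samples.
#' @export
resample_trajectory <- function(traj, n, params) {
  tt <- seq(traj$t[1], traj$t[length(traj$t)], length.out = n)
  fq <- apply(traj$q, 2, function(y) stats::splinefun(traj$t, y))
  q <- sapply(fq, function(f) f(tt))
  reach_trajectory(tt, q,
                   sapply(fq, function(f) f(tt, deriv = 1)),
                   sapply(fq, function(f) f(tt, deriv = 2)),
                   sapply(fq, function(f) f(tt, deriv = 3)),
                   params)
}

#' @export
print.reach_trajectory <- function(x, ...) {
  n <- length(x$t)
  d <- sqrt(sum((x$hand$p[n, ] - x$hand$p[1, ])^2))
  cat(sprintf("reach_trajectory: %d samples, T = %.3f s, chord %.3f m, peak speed %.3f m/s\n",
              n, x$T, d, max(hand_speed(x))))
  invisible(x)
}
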