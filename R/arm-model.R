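#' Anthropometric parameters of the planar two-link arm
#'
#' Builds the parameter set of a two-joint (shoulder, elbow) rigid arm moving
#' in the vertical para-sagittal plane. Segment 1 is the upper arm, segment 2
#' the forearm+hand (the fingertip sits at its distal end). Defaults follow
#' Winter-style anthropometric scaling from body mass and height; every
#' quantity can be overridden individually, so subject-specific parameter
#' sets are obtained by passing the subject's measurements.
#'
#' @param mass body mass (kg).
#' @param height body height (m).
#' @param l1,l2 segment lengths (m): upper arm, forearm+hand.
#' @param m1,m2 segment masses (kg).
#' @param lc1,lc2 distance from the proximal joint to the segment centre of
#'   mass (m).
#' @param I1,I2 segment moments of inertia about the centre of mass (kg m^2).
#' @param B 2x2 joint viscosity matrix (N m s/rad), symmetric positive
#'   semi-definite.
#' @param g gravitational acceleration (m/s^2, positive; use 0 for
#'   horizontal-plane movements).
#' @param joint_lower,joint_upper joint limits (rad), `[shoulder, elbow]`.
#'   The shoulder angle is measured counterclockwise from the forward
#'   (antero-posterior, +x) horizontal axis; the elbow angle is the flexion
#'   angle from the upper-arm extension (0 = arm fully extended).
#' @param u_max bound on the motor command (torque acceleration, N m/s^2).
#' @return An object of class `arm_params`: a list with the fields above plus
#'   the total arm length `L = l1 + l2`.
#' @examples
#' par <- arm_params()
#' par$L
#' forward_kinematics(c(0, pi / 2), par)$p
#' @export
arm_params <- function(mass = 70, height = 1.75,
                       l1 = 0.186 * height, l2 = 0.254 * height,
                       m1 = 0.028 * mass, m2 = 0.022 * mass,
                       lc1 = 0.436 * l1, lc2 = 0.682 * l2,
                       I1 = m1 * (0.322 * l1)^2, I2 = m2 * (0.468 * l2)^2,
                       B = matrix(c(0.05, 0.025, 0.025, 0.05), 2, 2),
                       g = 9.81,
                       joint_lower = c(-pi / 2, 0),
                       joint_upper = c(pi, 2.8),
                       u_max = 10000) {
  stopifnot(l1 > 0, l2 > 0, m1 > 0, m2 > 0, I1 > 0, I2 > 0,
            lc1 > 0, lc2 > 0, lc1 <= l1, lc2 <= l2, g >= 0, u_max > 0)
  B <- as.matrix(B)
  if (!isTRUE(all.equal(B, t(B))) || any(eigen(B, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-12))
    stop("viscosity matrix B must be symmetric positive semi-definite")
  p <- list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, lc1 = lc1, lc2 = lc2,
            I1 = I1, I2 = I2, B = B, g = g, L = l1 + l2,
            joint_lower = joint_lower, joint_upper = joint_upper,
            u_max = u_max)
  class(p) <- "arm_params"
  p
}

#' @export
print.arm_params <- function(x, ...) {
  cat("Planar two-link arm\n")
  cat(sprintf("  segments: l1=%.3f m (m1=%.2f kg), l2=%.3f m (m2=%.2f kg), L=%.3f m\n",
              x$l1, x$m1, x$l2, x$m2, x$L))
  cat(sprintf("  inertia:  I1=%.4f, I2=%.4f kg m^2; lc1=%.3f, lc2=%.3f m\n",
              x$I1, x$I2, x$lc1, x$lc2))
  cat(sprintf("  g=%.2f m/s^2, |u|<=%g N m/s^2\n", x$g, x$u_max))
  invisible(x)
}

# Lumped dynamic coefficients of the two-link chain:
#   M(q) = [a1 + 2 a2 cos q2, a3 + a2 cos q2; a3 + a2 cos q2, a3]
.dyn_coefs <- function(params) {
  list(a1 = params$I1 + params$I2 + params$m1 * params$lc1^2 +
         params$m2 * (params$l1^2 + params$lc2^2),
       a2 = params$m2 * params$l1 * params$lc2,
       a3 = params$I2 + params$m2 * params$lc2^2,
       g1 = params$g * (params$m1 * params$lc1 + params$m2 * params$l1),
       g2 = params$g * params$m2 * params$lc2)
}

.as_qmat <- function(q) {
  if (is.null(dim(q))) matrix(q, ncol = 2) else as.matrix(q)
}

#' Inertia matrix of the arm
#'
#' @param q joint angles, length-2 vector.
#' @param params an [arm_params()] object.
#' @return the symmetric positive definite 2x2 inertia matrix `M(q)`.
#' @export
inertia_matrix <- function(q, params) {
  co <- .dyn_coefs(params)
  c2 <- cos(q[2])
  matrix(c(co$a1 + 2 * co$a2 * c2, co$a3 + co$a2 * c2,
           co$a3 + co$a2 * c2, co$a3), 2, 2)
}

#' Gravitational torque vector
#'
#' @inheritParams inertia_matrix
#' @param q joint angles; a length-2 vector or an n x 2 matrix.
#' @return gravity torques `G(q)`, same shape as `q`.
#' @export
gravity_torque <- function(q, params) {
  co <- .dyn_coefs(params)
  q <- .as_qmat(q)
  c1 <- cos(q[, 1]); c12 <- cos(q[, 1] + q[, 2])
  out <- cbind(co$g1 * c1 + co$g2 * c12, co$g2 * c12)
  if (nrow(out) == 1) drop(out) else out
}

#' Forward kinematics of the fingertip
#'
#' Maps joint angles (and, optionally, their time derivatives) to the
#' fingertip position in the vertical plane (x antero-posterior, z vertical,
#' shoulder at the origin), with velocity, acceleration and jerk obtained by
#' the chain rule. Vectorized over rows.
#'
#' @param q joint angles (rad), length-2 vector or n x 2 matrix
#'   `[shoulder, elbow]`.
#' @param params an [arm_params()] object.
#' @param qdot,qddot,qdddot optional joint velocity, acceleration, jerk with
#'   the same shape as `q`.
#' @return A list with matrices (n x 2, columns x and z) `p`, and `v`, `a`,
#'   `j` when the corresponding joint derivatives were supplied.
#' @examples
#' par <- arm_params(l1 = 0.30, l2 = 0.35)
#' forward_kinematics(c(0, 0), par)$p # fully extended along x
#' @export
forward_kinematics <- function(q, params, qdot = NULL, qddot = NULL,
                               qdddot = NULL) {
  q <- .as_qmat(q)
  stopifnot(all(is.finite(q)))
  # complex representation: p = l1 e^{i th1} + l2 e^{i th2}, th2 = q1 + q2
  th1 <- q[, 1]; th2 <- q[, 1] + q[, 2]
  e1 <- exp(1i * th1); e2 <- exp(1i * th2)
  cplx <- function(z) cbind(Re(z), Im(z))
  out <- list(p = cplx(params$l1 * e1 + params$l2 * e2))
  if (!is.null(qdot)) {
    qdot <- .as_qmat(qdot)
    w1 <- qdot[, 1]; w2 <- qdot[, 1] + qdot[, 2]
    out$v <- cplx(params$l1 * 1i * w1 * e1 + params$l2 * 1i * w2 * e2)
    if (!is.null(qddot)) {
      qddot <- .as_qmat(qddot)
      d1 <- qddot[, 1]; d2 <- qddot[, 1] + qddot[, 2]
      out$a <- cplx(params$l1 * (1i * d1 - w1^2) * e1 +
                      params$l2 * (1i * d2 - w2^2) * e2)
      if (!is.null(qdddot)) {
        qdddot <- .as_qmat(qdddot)
        j1 <- qdddot[, 1]; j2 <- qdddot[, 1] + qdddot[, 2]
        out$j <- cplx(params$l1 * (1i * j1 - 3 * w1 * d1 - 1i * w1^3) * e1 +
                        params$l2 * (1i * j2 - 3 * w2 * d2 - 1i * w2^3) * e2)
      }
    }
  }
  out
}

#' Inverse kinematics of the fingertip
#'
#' Recovers the joint angles putting the fingertip at a given planar
#' position. The default branch is elbow flexion in `[0, pi]` ("up" in the
#' flexion-positive convention); the mirror branch negates the elbow angle.
#'
#' @param p fingertip position (m), length-2 vector `c(x, z)` or n x 2 matrix.
#' @param params an [arm_params()] object.
#' @param branch `"up"` (default, elbow angle in `[0, pi]`) or `"down"`.
#' @return joint angles, same shape as `p`.
#' @export
inverse_kinematics <- function(p, params, branch = c("up", "down")) {
  branch <- match.arg(branch)
  p <- .as_qmat(p)
  r2 <- p[, 1]^2 + p[, 2]^2
  r <- sqrt(r2)
  rmax <- params$l1 + params$l2
  rmin <- abs(params$l1 - params$l2)
  tol <- 1e-9
  if (any(r > rmax + tol))
    stop(sprintf("point at distance %.4f m beyond reach |p| <= l1+l2 = %.4f m",
                 max(r), rmax))
  if (any(r < rmin - tol))
    stop(sprintf("point at distance %.4f m inside inner annulus bound |l1-l2| = %.4f m",
                 min(r), rmin))
  cq2 <- pmin(1, pmax(-1, (r2 - params$l1^2 - params$l2^2) /
                        (2 * params$l1 * params$l2)))
  q2 <- acos(cq2)
  if (branch == "down") q2 <- -q2
  q1 <- atan2(p[, 2], p[, 1]) -
    atan2(params$l2 * sin(q2), params$l1 + params$l2 * cos(q2))
  out <- cbind(q1, q2)
  dimnames(out) <- NULL
  if (nrow(out) == 1) drop(out) else out
}

#' Inverse dynamics
#'
#' Torques realizing a joint motion:
#' `tau = M(q) qddot + C(q, qdot) qdot + G(q) + B qdot`.
#' Vectorized over rows.
#'
#' @param q,qdot,qddot joint angles, velocities, accelerations; length-2
#'   vectors or n x 2 matrices.
#' @param params an [arm_params()] object.
#' @return joint torques (N m), same shape as inputs.
#' @export
inverse_dynamics <- function(q, qdot, qddot, params) {
  co <- .dyn_coefs(params)
  q <- .as_qmat(q); qdot <- .as_qmat(qdot); qddot <- .as_qmat(qddot)
  c2 <- cos(q[, 2]); s2 <- sin(q[, 2])
  m11 <- co$a1 + 2 * co$a2 * c2
  m12 <- co$a3 + co$a2 * c2
  w1 <- qdot[, 1]; w2 <- qdot[, 2]
  # Coriolis/centripetal (standard Christoffel convention):
  h1 <- -co$a2 * s2 * w2 * (2 * w1 + w2)
  h2 <- co$a2 * s2 * w1^2
  c1 <- cos(q[, 1]); c12 <- cos(q[, 1] + q[, 2])
  B <- params$B
  tau1 <- m11 * qddot[, 1] + m12 * qddot[, 2] + h1 +
    co$g1 * c1 + co$g2 * c12 + B[1, 1] * w1 + B[1, 2] * w2
  tau2 <- m12 * qddot[, 1] + co$a3 * qddot[, 2] + h2 +
    co$g2 * c12 + B[2, 1] * w1 + B[2, 2] * w2
  out <- cbind(tau1, tau2)
  dimnames(out) <- NULL
  if (nrow(out) == 1) drop(out) else out
}

#' Analytic torque rate along a joint motion
#'
#' Time derivative of the inverse-dynamics map, used to evaluate the
#' torque-change cost and the actuator state without numerical
#' differentiation of the torques.
#'
#' @param q,qdot,qddot,qdddot joint kinematics up to jerk (n x 2 or length 2).
#' @param params an [arm_params()] object.
#' @return torque rates (N m/s), same shape as inputs.
#' @export
torque_rate <- function(q, qdot, qddot, qdddot, params) {
  co <- .dyn_coefs(params)
  q <- .as_qmat(q); qdot <- .as_qmat(qdot)
  qddot <- .as_qmat(qddot); qdddot <- .as_qmat(qdddot)
  c2 <- cos(q[, 2]); s2 <- sin(q[, 2])
  w1 <- qdot[, 1]; w2 <- qdot[, 2]
  d1 <- qddot[, 1]; d2 <- qddot[, 2]
  m11 <- co$a1 + 2 * co$a2 * c2
  m12 <- co$a3 + co$a2 * c2
  # Mdot qddot
  dm11 <- -2 * co$a2 * s2 * w2
  dm12 <- -co$a2 * s2 * w2
  # d/dt of Coriolis terms h1, h2 (see inverse_dynamics)
  dh1 <- -co$a2 * (c2 * w2^2 * (2 * w1 + w2) +
                     s2 * (d2 * (2 * w1 + w2) + w2 * (2 * d1 + d2)))
  dh2 <- co$a2 * (c2 * w2 * w1^2 + s2 * 2 * w1 * d1)
  s1 <- sin(q[, 1]); s12 <- sin(q[, 1] + q[, 2])
  dg1 <- -co$g1 * s1 * w1 - co$g2 * s12 * (w1 + w2)
  dg2 <- -co$g2 * s12 * (w1 + w2)
  B <- params$B
  td1 <- dm11 * d1 + dm12 * d2 + m11 * qdddot[, 1] + m12 * qdddot[, 2] +
    dh1 + dg1 + B[1, 1] * d1 + B[1, 2] * d2
  td2 <- dm12 * d1 + co$a3 * qdddot[, 2] + m12 * qdddot[, 1] +
    dh2 + dg2 + B[2, 1] * d1 + B[2, 2] * d2
  out <- cbind(td1, td2)
  dimnames(out) <- NULL
  if (nrow(out) == 1) drop(out) else out
}

#' State derivative of the controlled arm
#'
#' Right-hand side of the arm's state-space model: rigid-body dynamics plus
#' the torque-derivative actuator, with motor command `u` acting as the
#' torque acceleration. The state is `(q, qdot, tau, taudot)`.
#'
#' @param state a list with fields `q`, `qdot`, `tau`, `taudot` (length-2
#'   numeric vectors).
#' @param u motor command (N m/s^2), length-2.
#' @param params an [arm_params()] object.
#' @return a list with fields `qdot`, `qddot`, `taudot`, `taudotdot` — the
#'   time derivative of each state block.
#' @export
dynamics_rhs <- function(state, u, params) {
  with(state, {
    if (!all(is.finite(c(q, qdot, tau, taudot, u))))
      stop("non-finite state or control")
    co <- .dyn_coefs(params)
    c2 <- cos(q[2]); s2 <- sin(q[2])
    M <- matrix(c(co$a1 + 2 * co$a2 * c2, co$a3 + co$a2 * c2,
                  co$a3 + co$a2 * c2, co$a3), 2, 2)
    h <- c(-co$a2 * s2 * qdot[2] * (2 * qdot[1] + qdot[2]),
           co$a2 * s2 * qdot[1]^2)
    G <- c(co$g1 * cos(q[1]) + co$g2 * cos(q[1] + q[2]),
           co$g2 * cos(q[1] + q[2]))
    qddot <- drop(solve(M, tau - h - G - params$B %*% qdot))
    list(qdot = qdot, qddot = qddot, taudot = taudot, taudotdot = u)
  })
}

# Total mechanical energy (kinetic + gravitational potential), for
# energy-balance checks.
.mechanical_energy <- function(q, qdot, params) {
  co <- .dyn_coefs(params)
  q <- .as_qmat(q); qdot <- .as_qmat(qdot)
  c2 <- cos(q[, 2])
  m11 <- co$a1 + 2 * co$a2 * c2
  m12 <- co$a3 + co$a2 * c2
  ke <- 0.5 * (m11 * qdot[, 1]^2 + 2 * m12 * qdot[, 1] * qdot[, 2] +
                 co$a3 * qdot[, 2]^2)
  pe <- co$g1 * sin(q[, 1]) + co$g2 * sin(q[, 1] + q[, 2])
  ke + pe
}
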