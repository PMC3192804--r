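#' Canonical basis-cost identifiers
#'
#' The eight classical movement cost functionals, in their fixed order:
#' `hand_jerk`, `angle_jerk`, `angle_accel`, `torque_change`, `torque`,
#' `geodesic`, `energy`, `effort`. This order indexes every weight vector
#' in the package.
#'
#' @return character vector of length 8.
#' @export
cost_names <- function() {
  c("hand_jerk", "angle_jerk", "angle_accel", "torque_change",
    "torque", "geodesic", "energy", "effort")
}

.cost_index <- function(index) {
  if (is.character(index)) {
    i <- match(index, cost_names())
    if (is.na(i)) stop("unknown basis cost: ", index)
    i
  } else {
    i <- as.integer(index)
    if (i < 1 || i > 8) stop("basis cost index out of range: ", index)
    i
  }
}

#' Weight vector over the basis costs
#'
#' A composite movement cost is the weighted linear combination
#' `sum_i alpha_i * s_i * C_i` of the eight basis costs. `s` is a positive
#' re-scaling vector (typically the reciprocal of single-cost optimal
#' magnitudes, see [compute_rescaling()]) that puts the basis costs on a
#' common O(1) scale; `anchor` names the component held fixed at 1 during
#' inverse optimization, since weight vectors are only identified up to a
#' common positive factor.
#'
#' @param alpha non-negative weights; either a full named/unnamed 8-vector
#'   (order of [cost_names()]) or a named vector of the non-zero entries,
#'   e.g. `c(energy = 10, angle_accel = 1)`.
#' @param s positive re-scaling factors, length 8 (default all 1).
#' @param anchor basis-cost id whose weight is held at 1 during inversion.
#' @return an object of class `cost_weights`.
#' @examples
#' cost_weights(c(angle_accel = 1, energy = 10))
#' @export
cost_weights <- function(alpha, s = rep(1, 8), anchor = "angle_accel") {
  if (!is.null(names(alpha)) && length(alpha) < 8) {
    a <- stats::setNames(numeric(8), cost_names())
    bad <- setdiff(names(alpha), cost_names())
    if (length(bad)) stop("unknown basis cost: ", paste(bad, collapse = ", "))
    a[names(alpha)] <- alpha
    alpha <- a
  }
  alpha <- stats::setNames(as.numeric(alpha), cost_names())
  stopifnot(length(alpha) == 8, length(s) == 8)
  if (any(alpha < 0)) stop("weights must be non-negative")
  if (all(alpha == 0)) stop("at least one weight must be positive")
  if (any(s <= 0)) stop("re-scaling factors must be positive")
  structure(list(alpha = alpha, s = stats::setNames(as.numeric(s), cost_names()),
                 anchor = .cost_index(anchor)),
            class = "cost_weights")
}

#' @export
print.cost_weights <- function(x, ...) {
  nz <- x$alpha[x$alpha > 0]
  cat("cost_weights:", paste(sprintf("%s=%.4g", names(nz), nz), collapse = ", "),
      sprintf("(anchor: %s)\n", cost_names()[x$anchor]))
  invisible(x)
}

# Evaluate all eight basis costs along a trajectory in one pass.
# eps smooths the nondifferentiable geodesic and absolute-work integrands.
.basis_cost_values <- function(traj, params, eps = 1e-6) {
  w <- traj$quad_w
  co <- .dyn_coefs(params)
  qd <- traj$qd
  m11 <- co$a1 + 2 * co$a2 * cos(traj$q[, 2])
  m12 <- co$a3 + co$a2 * cos(traj$q[, 2])
  ke2 <- m11 * qd[, 1]^2 + 2 * m12 * qd[, 1] * qd[, 2] + co$a3 * qd[, 2]^2
  pow <- traj$tau * qd
  c(hand_jerk = sum(w * rowSums(traj$hand$j^2)),
    angle_jerk = sum(w * rowSums(traj$qddd^2)),
    angle_accel = sum(w * rowSums(traj$qdd^2)),
    torque_change = sum(w * rowSums(traj$taud^2)),
    torque = sum(w * rowSums(traj$tau^2)),
    geodesic = sum(w * sqrt(pmax(ke2, 0) + eps)),
    energy = sum(w * (sqrt(pow[, 1]^2 + eps^2) + sqrt(pow[, 2]^2 + eps^2))),
    effort = sum(w * rowSums(traj$u^2)))
}

#' Evaluate one basis cost on a trajectory
#'
#' The integrands, integrated over the movement: hand jerk
#' `||fingertip jerk||^2`; angle jerk `||q'''||^2`; angle acceleration
#' `||q''||^2`; torque change `||tau'||^2`; torque `||tau||^2`; geodesic
#' `sqrt(q' M(q) q')` (path length under the kinetic-energy metric); energy
#' `sum_i |tau_i q'_i|` (total absolute work, the mechanical energy actually
#' spent); effort `||u||^2` (squared motor command). Quadrature uses the
#' weights stored with the trajectory (trapezoidal by default, Gauss when
#' the grid is solver-native).
#'
#' @param traj a [reach_trajectory()].
#' @param index basis-cost id (string from [cost_names()]) or integer 1..8.
#' @param params an [arm_params()] object.
#' @param eps smoothing parameter for the nondifferentiable geodesic and
#'   absolute-work integrands (`>= 0`; the exact costs are the limit
#'   `eps -> 0`).
#' @return non-negative scalar.
#' @export
evaluate_basis_cost <- function(traj, index, params, eps = 1e-6) {
  stopifnot(eps >= 0)
  unname(.basis_cost_values(traj, params, eps)[.cost_index(index)])
}

#' All eight basis costs of a trajectory
#' @inheritParams evaluate_basis_cost
#' @return named numeric vector of length 8.
#' @export
all_basis_costs <- function(traj, params, eps = 1e-6) {
  stopifnot(eps >= 0)
  .basis_cost_values(traj, params, eps)
}

#' Composite (hybrid) movement cost
#'
#' `sum_i alpha_i s_i C_i(traj)` — linear in the weight vector.
#'
#' @inheritParams evaluate_basis_cost
#' @param weights a [cost_weights()] object.
#' @return scalar cost.
#' @export
composite_cost <- function(traj, weights, params, eps = 1e-6) {
  stopifnot(inherits(weights, "cost_weights"))
  sum(weights$alpha * weights$s * .basis_cost_values(traj, params, eps))
}

#' Relative contribution of each basis cost to a composite cost
#'
#' Fractions `alpha_i s_i C_i / sum_j alpha_j s_j C_j`, which sum to 1. The
#' weight vector alone does not reveal how much each ingredient shapes the
#' movement, because the basis costs have very different magnitudes; the
#' contributions do.
#'
#' @param solution an `ocp_solution` (from [solve_ocp()]) or a
#'   [reach_trajectory()].
#' @param weights a [cost_weights()] object.
#' @param params an [arm_params()] object; required when `solution` is a
#'   bare trajectory.
#' @param eps smoothing parameter, as in [evaluate_basis_cost()].
#' @return named vector of 8 fractions summing to 1.
#' @export
cost_contributions <- function(solution, weights, params = NULL, eps = 1e-6) {
  cb <- if (inherits(solution, "ocp_solution")) {
    solution$basis_costs
  } else {
    stopifnot(!is.null(params))
    .basis_cost_values(solution, params, eps)
  }
  terms <- weights$alpha * weights$s * cb
  tot <- sum(terms)
  if (tot <= 0) stop("composite cost is zero; contributions undefined")
  terms / tot
}
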