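#' Reaching task specification
#'
#' A rest-to-rest reaching task in fixed time: the arm starts at rest in
#' posture `q0` (zero velocity, gravity-compensating torque, zero torque
#' rate) and must end at rest on the target. A `bar` target is the vertical
#' line `x = d` (the fingertip height on the bar is free — the task is
#' redundant); a `point` target pins the fingertip.
#'
#' @param q0 initial joint posture (rad), length 2.
#' @param target either `bar_target(d)` or `point_target(p)`.
#' @param T movement duration (s).
#' @param label optional posture label (e.g. "P1").
#' @return an object of class `task_spec`.
#' @seealso [bar_target()], [point_target()], [solve_ocp()]
#' @export
task_spec <- function(q0, target, T = 0.7, label = NULL) {
  stopifnot(length(q0) == 2, is.finite(q0), T > 0,
            inherits(target, "reach_target"))
  structure(list(q0 = as.numeric(q0), target = target, T = T,
                 label = label), class = "task_spec")
}

#' @rdname task_spec
#' @param d horizontal shoulder-to-bar distance (m); must be smaller than
#'   the arm length for the bar to be reachable.
#' @export
bar_target <- function(d) {
  stopifnot(d > 0)
  structure(list(type = "bar", d = d), class = "reach_target")
}

#' @rdname task_spec
#' @param p fingertip target position `c(x, z)` (m).
#' @export
point_target <- function(p) {
  stopifnot(length(p) == 2, is.finite(p))
  structure(list(type = "point", p = as.numeric(p)), class = "reach_target")
}

#' @export
print.task_spec <- function(x, ...) {
  tg <- if (x$target$type == "bar") sprintf("bar at x = %.3f m", x$target$d)
        else sprintf("point (%.3f, %.3f) m", x$target$p[1], x$target$p[2])
  cat(sprintf("task%s: q0 = (%.1f, %.1f) deg, T = %.2f s, target: %s\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$q0[1] * 180 / pi, x$q0[2] * 180 / pi, x$T, tg))
  invisible(x)
}

#' Options of the direct optimal-control solver
#'
#' @param nodes number of quadrature nodes (>= 10). The spline basis size
#'   scales with it (roughly `nodes/4` free functions per joint).
#' @param scheme quadrature rule: `"gauss"` (Gauss-Legendre nodes and
#'   weights) or `"trapezoid"` (uniform grid).
#' @param eps_schedule decreasing smoothing parameters for the
#'   nondifferentiable geodesic/absolute-work integrands; the problem is
#'   re-solved once per value with warm starts (continuation).
#' @param maxit iteration cap of the inner quasi-Newton solve.
#' @param n_out number of samples of the returned trajectory.
#' @param multistart number of perturbed restarts attempted when a solve
#'   fails to improve.
#' @param penalty weight of the joint-limit / control-bound penalty.
#' @param smooth_reg relative weight of the acceleration regularizer added
#'   when only nondifferentiable integrands (geodesic, absolute work) are
#'   being minimized. Those integrands vanish wherever the arm is at rest,
#'   so a discretized minimizer can "park" on the quadrature nodes while
#'   oscillating between them; a small coercive smoothness term removes
#'   this spurious freedom. Expressed as a fraction of the initial
#'   objective (default 1e-3); not included in reported costs.
#' @param factr relative-improvement stopping tolerance of the inner
#'   quasi-Newton solve (as in [stats::optim()]'s L-BFGS-B; multiples of
#'   machine epsilon). Larger values stop earlier - useful inside the
#'   inverse loop where millimetre accuracy suffices.
#' @param init optional warm start: a list with elements `coefs` (K x 2
#'   matrix) and, for bar tasks, `z_f`.
#' @return an object of class `solver_options`.
#' @export
solver_options <- function(nodes = 40, scheme = c("gauss", "trapezoid"),
                           eps_schedule = c(1e-2, 1e-4, 1e-6),
                           maxit = 400, n_out = 201, multistart = 3,
                           penalty = 1e3, smooth_reg = 1e-3, factr = 1e7,
                           init = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(nodes >= 10, maxit >= 10, n_out >= 20, smooth_reg >= 0,
            all(diff(eps_schedule) < 0) || length(eps_schedule) == 1)
  structure(list(nodes = as.integer(nodes), scheme = scheme,
                 eps_schedule = eps_schedule, maxit = as.integer(maxit),
                 n_out = as.integer(n_out), multistart = as.integer(multistart),
                 penalty = penalty, smooth_reg = smooth_reg, factr = factr,
                 init = init),
            class = "solver_options")
}

# --- spline transcription machinery ------------------------------------

# Boundary polynomial sigma(s) = 15 s^4 - 24 s^5 + 10 s^6: the minimal
# polynomial ramp with sigma(0)=0, sigma(1)=1, zero 1st-3rd derivatives at
# s=0 and zero 1st-2nd derivatives at s=1 (rest-to-rest with zero initial
# torque rate; terminal torque rate free).
.sigma_derivs <- function(s) {
  list(d0 = 15 * s^4 - 24 * s^5 + 10 * s^6,
       d1 = 60 * s^3 - 120 * s^4 + 60 * s^5,
       d2 = 180 * s^2 - 480 * s^3 + 300 * s^4,
       d3 = 360 * s - 1440 * s^2 + 1200 * s^3,
       d4 = 360 - 2880 * s + 3600 * s^2)
}

# Free-basis: degree-6 B-splines; the first 4 and last 3 B-splines are
# dropped so every basis function has value and 1st-3rd derivatives zero at
# s=0 and value and 1st-2nd derivatives zero at s=1. Knot layout is hybrid:
# a few geometrically graded knots at each end resolve the thin boundary
# layer induced by the zero-initial-jerk rest condition, while the
# remaining knots are uniform so the mid-movement path keeps full
# resolution (all-geometric grading starves the interior and visibly
# distorts the speed profile).
.ocp_knots <- function(K, n_edge = 3, edge = 0.05, ratio = 0.25) {
  n_edge <- min(n_edge, floor((K - 2) / 2))  # always keep >= 2 interior knots
  left <- edge * ratio^(seq(n_edge - 1, 0))
  ni <- K - 2 * n_edge
  interior <- if (ni > 0) seq(edge, 1 - edge, length.out = ni + 2)[2:(ni + 1)]
  ik <- sort(unique(c(left, interior, 1 - left)))
  c(rep(0, 7), ik, rep(1, 7))
}

.basis_cache <- new.env(parent = emptyenv())

# Per-basis normalization: clustered-knot splines have jerk seminorms
# spanning many orders of magnitude; dividing each basis function by its
# jerk seminorm makes smoothness-type costs near-isotropic in the
# coefficients, which quasi-Newton iteration needs. Deterministic given K,
# so warm-start coefficients transfer between node sets.
.basis_scale <- function(K) {
  knots <- .ocp_knots(K)
  nb <- length(knots) - 7
  keep <- 5:(nb - 3)
  sf <- seq(0, 1, length.out = 2001)
  d3 <- splines::splineDesign(knots, sf, ord = 7, derivs = rep(3, length(sf)),
                              outer.ok = TRUE)[, keep, drop = FALSE]
  w <- .trapz_weights(sf)
  1 / sqrt(pmax(colSums(w * d3^2), 1e-300))
}

# Basis value/derivative matrices (derivatives w.r.t. normalized time s)
# at the given s nodes, cached.
.ocp_basis <- function(K, s, tag) {
  key <- paste0(tag, "_", K, "_", length(s))
  hit <- .basis_cache[[key]]
  if (!is.null(hit) && isTRUE(all.equal(hit$s, s))) return(hit)
  knots <- .ocp_knots(K)
  nb <- length(knots) - 7
  keep <- 5:(nb - 3)
  scale <- .basis_scale(K)
  B <- lapply(0:4, function(d)
    splines::splineDesign(knots, s, ord = 7, derivs = rep(d, length(s)),
                          outer.ok = TRUE)[, keep, drop = FALSE] %*% diag(scale))
  out <- list(s = s, B = B, sg = .sigma_derivs(s), K = K)
  .basis_cache[[key]] <- out
  out
}

# Composite quadrature matched to the spline basis: a fixed-order rule on
# each knot interval, so the graded boundary intervals are fully resolved
# (a single global rule would alias the boundary layer between its nodes).
.ocp_quadrature <- function(K, scheme, nodes) {
  bp <- c(0, .ocp_knots(K)[8:(7 + K)], 1)
  # at least 7 points per interval: a degree-6 spline piece cannot vanish at
  # 7 nodes, so minimizers cannot hide motion between quadrature points
  p <- max(7L, as.integer(round(nodes / (K + 1))))
  if (scheme == "gauss") {
    gl <- pracma::gaussLegendre(p, 0, 1)
    s <- as.vector(vapply(seq_len(K + 1), function(i)
      bp[i] + (bp[i + 1] - bp[i]) * gl$x, numeric(p)))
    w <- as.vector(vapply(seq_len(K + 1), function(i)
      (bp[i + 1] - bp[i]) * gl$w, numeric(p)))
  } else {
    p <- max(4L, p)
    s <- unique(as.vector(vapply(seq_len(K + 1), function(i)
      seq(bp[i], bp[i + 1], length.out = p), numeric(p))))
    w <- .trapz_weights(s)
  }
  list(s = s, w = w)
}

.reach_halfspan <- function(params, d) {
  if (d >= params$L) stop(sprintf(
    "bar at d = %.3f m is beyond the arm length L = %.3f m", d, params$L))
  sqrt(params$L^2 - d^2)
}

# Joint kinematics at the basis nodes for coefficients C (K x 2) and
# terminal posture qT. Derivatives are with respect to physical time.
.eval_joint <- function(bs, q0, qT, C, T) {
  dq <- qT - q0
  q <- matrix(q0, length(bs$s), 2, byrow = TRUE) +
    bs$sg$d0 %o% dq + bs$B[[1]] %*% C
  list(q = q,
       qd = (bs$sg$d1 %o% dq + bs$B[[2]] %*% C) / T,
       qdd = (bs$sg$d2 %o% dq + bs$B[[3]] %*% C) / T^2,
       qddd = (bs$sg$d3 %o% dq + bs$B[[4]] %*% C) / T^3)
}

# Composite cost + feasibility penalty at quadrature nodes, evaluated for
# a BATCH of parameter vectors at once (columns of par_mat). The joint path
# is linear in the spline coefficients, so every candidate's node values
# stack into one big vectorized dynamics/cost evaluation - this is what
# makes finite-difference gradients affordable (one stacked evaluation per
# gradient instead of 2p sequential ones).
.ocp_objective_batch <- function(par_mat, ctx, eps) {
  par_mat <- as.matrix(par_mat)
  m <- ncol(par_mat)
  N <- length(ctx$wq)
  K <- ctx$K
  # terminal postures per candidate
  if (ctx$bar) {
    zf <- par_mat[2 * K + 1, ]
    qT <- .as_qmat(inverse_kinematics(cbind(ctx$d, zf), ctx$params))
    Cs <- par_mat[seq_len(2 * K), , drop = FALSE]
  } else {
    qT <- matrix(ctx$qT, m, 2, byrow = TRUE)
    Cs <- par_mat
  }
  # spline coefficients: K x (2m), candidate-major [j1 cand1, j2 cand1, ...]
  Cstack <- matrix(Cs, K, 2 * m)
  dq <- t(qT) - ctx$q0          # 2 x m
  dq2 <- as.vector(dq)          # length 2m, same candidate-major order
  bs <- ctx$bs
  mk <- function(Bd, sgd, powT) {
    A <- Bd %*% Cstack + sgd %o% dq2          # N x 2m
    st <- function(cols) as.vector(A[, cols])
    cbind(st(seq(1, 2 * m, by = 2)), st(seq(2, 2 * m, by = 2))) / powT
  }
  q <- mk(bs$B[[1]], bs$sg$d0, 1) +
    matrix(ctx$q0, m * N, 2, byrow = TRUE)
  qd <- mk(bs$B[[2]], bs$sg$d1, ctx$T)
  qdd <- mk(bs$B[[3]], bs$sg$d2, ctx$T^2)
  qddd <- mk(bs$B[[4]], bs$sg$d3, ctx$T^3)
  qsum <- function(x) {  # stacked integrand (m*N) -> per-candidate integral
    dim(x) <- c(N, m)
    colSums(ctx$wq * x)
  }
  w <- ctx$weights
  a <- w$alpha * w$s
  val <- numeric(m)
  if (a[1] > 0) {
    hj <- forward_kinematics(q, ctx$params, qd, qdd, qddd)$j
    val <- val + a[1] * qsum(rowSums(hj^2))
  }
  if (a[2] > 0) val <- val + a[2] * qsum(rowSums(qddd^2))
  if (a[3] > 0 || ctx$reg > 0)
    val <- val + (a[3] + ctx$reg) * qsum(rowSums(qdd^2))
  if (any(a[c(4, 5, 7, 8)] > 0)) {
    tau <- .as_qmat(inverse_dynamics(q, qd, qdd, ctx$params))
    if (a[5] > 0) val <- val + a[5] * qsum(rowSums(tau^2))
    if (a[7] > 0) {
      pow <- tau * qd
      val <- val + a[7] * qsum(sqrt(pow[, 1]^2 + eps^2) +
                                 sqrt(pow[, 2]^2 + eps^2))
    }
    if (a[4] > 0 || a[8] > 0) {
      taud <- .as_qmat(torque_rate(q, qd, qdd, qddd, ctx$params))
      if (a[4] > 0) val <- val + a[4] * qsum(rowSums(taud^2))
      if (a[8] > 0) {
        u1 <- fd_derivative(ctx$tq, matrix(taud[, 1], N, m))
        u2 <- fd_derivative(ctx$tq, matrix(taud[, 2], N, m))
        val <- val + a[8] * (colSums(ctx$wq * u1^2) + colSums(ctx$wq * u2^2))
        pen_u <- (colSums(ctx$wq * pmax(abs(u1) - ctx$params$u_max, 0)^2) +
                    colSums(ctx$wq * pmax(abs(u2) - ctx$params$u_max, 0)^2)) /
          ctx$params$u_max^2
        val <- val + ctx$fref * ctx$penalty * pen_u
      }
    }
  }
  if (a[6] > 0) {
    co <- .dyn_coefs(ctx$params)
    c2 <- cos(q[, 2])
    ke2 <- (co$a1 + 2 * co$a2 * c2) * qd[, 1]^2 +
      2 * (co$a3 + co$a2 * c2) * qd[, 1] * qd[, 2] + co$a3 * qd[, 2]^2
    val <- val + a[6] * qsum(sqrt(pmax(ke2, 0) + eps))
  }
  # joint-limit penalty (soft; solutions are normally interior)
  lo <- ctx$params$joint_lower; up <- ctx$params$joint_upper
  pen <- qsum(pmax(sweep(q, 2, up, "-"), 0)^2 %*% c(1, 1) +
                pmax(sweep(-q, 2, -lo, "-"), 0)^2 %*% c(1, 1))
  val + ctx$fref * ctx$penalty * pen
}

.ocp_objective <- function(par, ctx, eps) {
  .ocp_objective_batch(matrix(par, ncol = 1), ctx, eps)[1]
}

# batched central-difference gradient
.ocp_gradient <- function(par, ctx, eps, h = 1e-7) {
  p <- length(par)
  P <- matrix(par, p, 2 * p)
  idx <- cbind(rep(seq_len(p), each = 2), seq_len(2 * p))
  P[idx] <- P[idx] + rep(c(h, -h), p)
  v <- .ocp_objective_batch(P, ctx, eps)
  (v[seq(1, 2 * p, by = 2)] - v[seq(2, 2 * p, by = 2)]) / (2 * h)
}

#' Solve the direct optimal-control problem of a reaching task
#'
#' Finds the rest-to-rest trajectory minimizing the composite movement cost
#' under the arm dynamics, via an inverse-dynamics spline transcription:
#' joint paths are parameterized in a boundary-conforming spline basis (so
#' the rest boundary conditions and, for bar tasks, the on-bar terminal
#' constraint hold exactly), torques and motor commands are recovered from
#' the joint path by inverse dynamics (so the dynamics hold by
#' construction), and the remaining smooth finite-dimensional problem —
#' spline coefficients plus, for a bar task, the endpoint height on the bar
#' — is solved by bound-constrained quasi-Newton iteration, with a
#' continuation schedule on the smoothing parameter of the
#' nondifferentiable (geodesic, absolute-work) integrands.
#'
#' @param task a [task_spec()].
#' @param weights a [cost_weights()] object.
#' @param params an [arm_params()] object.
#' @param options a [solver_options()] object.
#' @return An object of class `ocp_solution`: list with `trajectory` (a
#'   [reach_trajectory()] on `n_out` samples), `cost` (composite cost of
#'   the returned trajectory), `basis_costs`, `contributions`,
#'   `residuals` (terminal velocity / acceleration / bar-distance), `z_f`
#'   (fingertip height at arrival), `status` and `diagnostics`, plus the
#'   spline `coefs` usable as a warm start.
#' @examples
#' \donttest{
#' par <- arm_params()
#' tk <- task_spec(inverse_kinematics(c(0.45, 0.15), par), bar_target(0.85 * par$L))
#' sol <- solve_ocp(tk, cost_weights(c(hand_jerk = 1)), par, solver_options(nodes = 24))
#' sol$z_f
#' }
#' @export
solve_ocp <- function(task, weights, params, options = solver_options()) {
  stopifnot(inherits(task, "task_spec"), inherits(weights, "cost_weights"),
            inherits(params, "arm_params"))
  bar <- task$target$type == "bar"
  K <- min(14L, max(6L, 2L * round(options$nodes / 8)))
  qd <- .ocp_quadrature(K, options$scheme, options$nodes)
  s_q <- qd$s; w_q <- qd$w
  bs <- .ocp_basis(K, s_q, options$scheme)
  q0 <- task$q0
  p0 <- forward_kinematics(q0, params)$p
  zr <- NULL
  if (bar) {
    d <- task$target$d
    zr <- .reach_halfspan(params, d)
  } else {
    qT <- inverse_kinematics(task$target$p, params)
  }
  ctx <- list(bs = bs, q0 = q0, T = task$T, params = params, weights = weights,
              K = K, bar = bar, wq = w_q * task$T, tq = s_q * task$T,
              penalty = options$penalty, fref = 1, reg = 0,
              d = if (bar) task$target$d else NA_real_,
              qT = if (bar) NULL else qT)
  # initial guess: straight ramp in joint space; bar endpoint at start height
  par0 <- rep(0, 2 * K)
  # coefficients are effectively unbounded (physical feasibility is kept by
  # the joint-limit penalty); only the bar height is box-constrained
  lower <- rep(-1e6, 2 * K); upper <- rep(1e6, 2 * K)
  if (bar) {
    zf0 <- min(max(p0[2], -0.98 * zr), 0.98 * zr)
    par0 <- c(par0, zf0)
    lower <- c(lower, -0.995 * zr); upper <- c(upper, 0.995 * zr)
  }
  if (!is.null(options$init)) {
    if (!is.null(options$init$coefs) && nrow(options$init$coefs) == K)
      par0[seq_len(2 * K)] <- as.vector(options$init$coefs)
    if (bar && !is.null(options$init$z_f))
      par0[2 * K + 1] <- min(max(options$init$z_f, lower[2 * K + 1]),
                             upper[2 * K + 1])
  }
  # Terms whose share of the objective at the initial guess is negligible
  # are dropped from the working objective: they cannot move the optimum
  # beyond solver tolerance, but microscopic kinks from near-zero-weight
  # nondifferentiable terms stall the line search well away from the
  # smooth minimum. Reported costs still use the caller's weights.
  eps_lo <- min(options$eps_schedule)
  jk0 <- .eval_joint(bs, q0,
                     if (bar) inverse_kinematics(c(ctx$d, par0[2 * K + 1]),
                                                 params) else qT,
                     matrix(par0[seq_len(2 * K)], K, 2), task$T)
  tr0q <- reach_trajectory(s_q * task$T, jk0$q, jk0$qd, jk0$qdd, jk0$qddd,
                           params, quad_w = w_q * task$T)
  terms0 <- weights$alpha * weights$s * .basis_cost_values(tr0q, params, eps_lo)
  tot0 <- sum(terms0)
  if (tot0 > 0) {
    w_eff <- weights
    w_eff$alpha[terms0 / tot0 < 1e-3] <- 0
    if (any(w_eff$alpha > 0)) ctx$weights <- w_eff
  }
  weights_eff <- ctx$weights
  f0 <- .ocp_objective(par0, ctx, eps_lo)
  ns_share <- if (tot0 > 0 && any(weights_eff$alpha[c(6, 7)] > 0))
    sum(terms0[c(6, 7)]) / tot0 else if (tot0 == 0) 0 else 0
  if (all(weights_eff$alpha[-c(6, 7)] == 0)) ns_share <- 1
  eps_seq <- if (ns_share > 1e-3) options$eps_schedule else eps_lo
  f0 <- .ocp_objective(par0, ctx, eps_seq[1])
  fref <- max(abs(f0), 1e-12)
  if (ns_share > 0.999 && options$smooth_reg > 0) {
    # acceleration regularizer against node-dodging (see solver_options)
    c3_0 <- sum(ctx$wq * rowSums(jk0$qdd^2))
    ctx$reg <- options$smooth_reg * fref / max(c3_0, 1e-12)
  }
  # penalty terms are multiplied by fref inside the objective so that, after
  # normalization by fref, they keep a fixed weight regardless of cost scale
  ctx$fref <- fref
  attempts <- 0; fevals <- 0
  run_solve <- function(par_start) {
    par <- par_start
    res <- NULL
    for (eps in eps_seq) {
      obj <- function(p) .ocp_objective(p, ctx, eps) / fref
      grd <- function(p) .ocp_gradient(p, ctx, eps) / fref
      res <- stats::optim(par, obj, grd, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = options$maxit,
                                         factr = options$factr %||% 1e7))
      par <- res$par
      fevals <<- fevals + res$counts[1]
    }
    res
  }
  # initial guesses: the base guess plus, for cold bar solves, endpoint
  # variants spread along the bar - several basis costs have multiple local
  # optima in the arrival height (e.g. gravity-exploiting descents), and
  # the sweep lets every mesh find the same global basin
  inits <- list(par0)
  if (bar && is.null(options$init) && options$multistart > 1) {
    for (zf_try in c(-0.6, 0.6) * zr) {
      pv <- par0; pv[2 * K + 1] <- zf_try
      inits <- c(inits, list(pv))
    }
  }
  best <- NULL; attempts <- 0
  for (pv in inits) {
    attempts <- attempts + 1
    res <- run_solve(pv)
    if (is.null(best) || res$value < best$value) best <- res
  }
  f_init <- f0 / fref
  while (best$value > f_init + 1e-10 && attempts < options$multistart) {
    # deterministic perturbations; no global RNG use inside the solver
    attempts <- attempts + 1
    pert <- 0.08 * sin(seq_along(par0) * 7.13 * attempts + 1.7)
    res2 <- run_solve(pmin(pmax(par0 + pert, lower), upper))
    if (res2$value < best$value) best <- res2
  }
  par <- best$par
  if (bar) {
    z_f <- par[length(par)]
    qT <- inverse_kinematics(c(ctx$d, z_f), params)
    C <- matrix(par[-length(par)], K, 2)
  } else {
    C <- matrix(par, K, 2)
    z_f <- forward_kinematics(qT, params)$p[2]
  }
  # dense output trajectory (exact basis evaluation)
  s_out <- seq(0, 1, length.out = options$n_out)
  bso <- .ocp_basis(K, s_out, "out")
  jk <- .eval_joint(bso, q0, qT, C, task$T)
  traj <- reach_trajectory(s_out * task$T, jk$q, jk$qd, jk$qdd, jk$qddd, params)
  eps_final <- min(eps_seq)
  # reported costs are evaluated on the solver's composite quadrature grid,
  # which resolves the boundary-layer jerk that a uniform grid misses
  jkq <- .eval_joint(bs, q0, qT, C, task$T)
  trq <- reach_trajectory(s_q * task$T, jkq$q, jkq$qd, jkq$qdd, jkq$qddd,
                          params, quad_w = w_q * task$T)
  basis_costs <- .basis_cost_values(trq, params, eps_final)
  cost <- sum(weights$alpha * weights$s * basis_costs)
  n <- options$n_out
  residuals <- c(term_speed = sqrt(sum(jk$qd[n, ]^2)),
                 term_accel = sqrt(sum(jk$qdd[n, ]^2)),
                 target = if (bar) abs(traj$hand$p[n, 1] - ctx$d)
                          else sqrt(sum((traj$hand$p[n, ] - task$target$p)^2)))
  # L-BFGS-B reports an abnormal line search (code 52) when it grinds into
  # the kink of an eps-smoothed integrand; the iterate is still a valid
  # minimizer candidate, so judge by achieved decrease instead
  status <- if (best$convergence %in% c(0, 1) ||
                best$value <= f_init + 1e-10) "success" else "failed"
  contributions <- {
    terms <- weights$alpha * weights$s * basis_costs
    if (sum(terms) > 0) terms / sum(terms) else terms
  }
  structure(list(trajectory = traj, cost = cost, basis_costs = basis_costs,
                 contributions = contributions, weights = weights,
                 task = task, residuals = residuals, status = status,
                 z_f = z_f, coefs = C,
                 diagnostics = list(objective = best$value * fref,
                                    convergence = best$convergence,
                                    message = best$message,
                                    fevals = unname(fevals),
                                    attempts = attempts, K = K,
                                    eps = eps_final)),
            class = "ocp_solution")
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat(sprintf("ocp_solution [%s]: cost = %.5g, z_f = %.3f m, residuals %.1e/%.1e/%.1e\n",
              x$status, x$cost, x$z_f, x$residuals[1], x$residuals[2],
              x$residuals[3]))
  nz <- x$contributions[x$contributions > 1e-3]
  if (length(nz))
    cat("  contributions:", paste(sprintf("%s %.1f%%", names(nz), 100 * nz),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Analytic minimum-jerk trajectory between two points
#'
#' The closed-form minimizer of the integrated squared fingertip jerk for a
#' rest-to-rest point-to-point movement: each Cartesian coordinate follows
#' the quintic profile `p0 + (pf - p0) (10 s^3 - 15 s^4 + 6 s^5)`,
#' `s = t/T`. Its jerk cost is `720 ||pf - p0||^2 / T^5` and its
#' peak-to-mean speed ratio is exactly 1.875, with peak speed at `T/2`.
#'
#' @param p0,pf start and end fingertip positions `c(x, z)` (m).
#' @param T duration (s).
#' @param n number of samples.
#' @param params optional [arm_params()]; when supplied the full-state
#'   trajectory (joints by inverse kinematics, exact chain-rule
#'   derivatives) is returned, otherwise a hand-level profile.
#' @return a [reach_trajectory()] when `params` is given; otherwise a list
#'   with fields `t`, `hand` (position/velocity/acceleration/jerk), `T`.
#' @export
min_jerk_analytic <- function(p0, pf, T, n = 201, params = NULL) {
  stopifnot(T > 0, n >= 5)
  s <- seq(0, 1, length.out = n)
  dp <- pf - p0
  sg <- list(d0 = 10 * s^3 - 15 * s^4 + 6 * s^5,
             d1 = (30 * s^2 - 60 * s^3 + 30 * s^4) / T,
             d2 = (60 * s - 180 * s^2 + 120 * s^3) / T^2,
             d3 = (60 - 360 * s + 360 * s^2) / T^3)
  p <- matrix(p0, n, 2, byrow = TRUE) + sg$d0 %o% dp
  v <- sg$d1 %o% dp; a <- sg$d2 %o% dp; j <- sg$d3 %o% dp
  if (is.null(params)) {
    return(list(t = s * T, hand = list(p = p, v = v, a = a, j = j), T = T,
                quad_w = .trapz_weights(s * T)))
  }
  .traj_from_hand_analytic(s * T, p, v, a, j, params)
}

# Joint kinematics from analytic hand kinematics by inverting the
# link-angle Jacobian (chain-rule, no numerical differentiation).
.traj_from_hand_analytic <- function(t, p, v, a, j, params, branch = "up") {
  q <- .as_qmat(inverse_kinematics(p, params, branch))
  th1 <- q[, 1]; th2 <- q[, 1] + q[, 2]
  e1 <- exp(1i * th1); e2 <- exp(1i * th2)
  n <- length(t)
  w <- d <- jj <- matrix(0, n, 2)  # link-angle derivative stacks
  for (i in seq_len(n)) {
    A <- cbind(c(Re(1i * params$l1 * e1[i]), Im(1i * params$l1 * e1[i])),
               c(Re(1i * params$l2 * e2[i]), Im(1i * params$l2 * e2[i])))
    w[i, ] <- solve(A, v[i, ])
    r2 <- a[i, ] + c(Re(params$l1 * w[i, 1]^2 * e1[i] +
                          params$l2 * w[i, 2]^2 * e2[i]),
                     Im(params$l1 * w[i, 1]^2 * e1[i] +
                          params$l2 * w[i, 2]^2 * e2[i]))
    d[i, ] <- solve(A, r2)
    z3 <- params$l1 * (3 * w[i, 1] * d[i, 1] + 1i * w[i, 1]^3) * e1[i] +
      params$l2 * (3 * w[i, 2] * d[i, 2] + 1i * w[i, 2]^3) * e2[i]
    jj[i, ] <- solve(A, j[i, ] + c(Re(z3), Im(z3)))
  }
  reach_trajectory(t, q,
                   cbind(w[, 1], w[, 2] - w[, 1]),
                   cbind(d[, 1], d[, 2] - d[, 1]),
                   cbind(jj[, 1], jj[, 2] - jj[, 1]), params)
}

#' Optimal-cost profile along the bar
#'
#' Discretizes the reachable region of the bar (the segment between the
#' intersections of the bar with the shoulder-centred circle of radius `L`)
#' and solves one fixed-endpoint problem per grid point, yielding the
#' movement cost as a function of the endpoint height. Also reports the
#' near-optimal set: heights whose cost is within a relative threshold of
#' the minimum (sub-optimality band).
#'
#' @param task a [task_spec()] with a bar target.
#' @param weights a [cost_weights()] object.
#' @param params an [arm_params()] object.
#' @param spacing grid spacing on the bar (m).
#' @param options a [solver_options()].
#' @param threshold relative sub-optimality threshold defining the
#'   near-optimal set (default 0.10).
#' @return a data.frame with columns `z`, `cost`, `ok`, `near_optimal`;
#'   attributes `z_min` (argmin), `cost_min`, and `reach_halfspan`.
#' @export
endpoint_cost_profile <- function(task, weights, params, spacing = 0.03,
                                  options = solver_options(),
                                  threshold = 0.10) {
  stopifnot(task$target$type == "bar", spacing > 0)
  d <- task$target$d
  zr <- .reach_halfspan(params, d)
  zs <- seq(-zr + 1e-6, zr - 1e-6, by = spacing)
  cost <- rep(NA_real_, length(zs)); ok <- logical(length(zs))
  init <- options$init
  for (i in seq_along(zs)) {
    tk <- task_spec(task$q0, point_target(c(d, zs[i])), task$T, task$label)
    oi <- options; oi$init <- init
    sol <- tryCatch(solve_ocp(tk, weights, params, oi), error = function(e) e)
    if (inherits(sol, "ocp_solution") && sol$status == "success") {
      cost[i] <- sol$cost; ok[i] <- TRUE
      init <- list(coefs = sol$coefs)  # continuation along the bar
    }
  }
  cmin <- min(cost, na.rm = TRUE)
  out <- data.frame(z = zs, cost = cost, ok = ok,
                    near_optimal = !is.na(cost) & cost <= (1 + threshold) * cmin)
  attr(out, "z_min") <- zs[which.min(cost)]
  attr(out, "cost_min") <- cmin
  attr(out, "reach_halfspan") <- zr
  out
}
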