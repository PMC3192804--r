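#' Trial-to-trial noise model for synthetic recordings
#'
#' Captures the statistical structure of recorded reaching-to-a-bar data:
#' endpoint scatter on the bar with vertical SD about three times the
#' antero-posterior SD, a smooth within-trial path perturbation, and
#' trial-to-trial duration variability.
#'
#' @param endpoint_sd_z vertical endpoint SD on the bar (m).
#' @param endpoint_sd_x antero-posterior endpoint SD (m).
#' @param kinematic_sd amplitude of the smooth within-trial path
#'   perturbation (m).
#' @param duration_cv coefficient of variation of trial durations (< 0.5).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(endpoint_sd_z = 0.03, endpoint_sd_x = 0.01,
                        kinematic_sd = 0.005, duration_cv = 0.1, seed = 1L) {
  stopifnot(endpoint_sd_z >= 0, endpoint_sd_x >= 0, kinematic_sd >= 0,
            duration_cv >= 0, duration_cv < 0.5)
  structure(list(endpoint_sd_z = endpoint_sd_z, endpoint_sd_x = endpoint_sd_x,
                 kinematic_sd = kinematic_sd, duration_cv = duration_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Default starting postures P1-P5
#'
#' Five rest postures spanning hand positions above, level with and below
#' the shoulder, each paired with the vertical bar placed at 85% of the
#' arm length. Start positions are expressed as fractions of the arm
#' length, so the set adapts to any subject's anthropometry.
#'
#' @param params an [arm_params()] object.
#' @param T movement duration (s).
#' @param d shoulder-bar distance (m); default 85% of arm length.
#' @return named list of five bar [task_spec()]s (P1..P5).
#' @export
default_postures <- function(params, T = 0.7, d = 0.85 * params$L) {
  rel <- list(P1 = c(0.325, 0.584), P2 = c(0.545, 0.234),
              P3 = c(0.519, -0.065), P4 = c(0.714, -0.455),
              P5 = c(0.623, -0.519))
  out <- lapply(names(rel), function(nm) {
    q0 <- inverse_kinematics(rel[[nm]] * params$L, params)
    task_spec(q0, bar_target(d), T, nm)
  })
  stats::setNames(out, names(rel))
}

# Quintic ramp used to translate a path toward a jittered endpoint while
# preserving rest boundary conditions.
.quintic_ramp <- function(s) {
  list(d0 = 10 * s^3 - 15 * s^4 + 6 * s^5,
       d1 = 30 * s^2 - 60 * s^3 + 30 * s^4,
       d2 = 60 * s - 180 * s^2 + 120 * s^3,
       d3 = 60 - 360 * s + 360 * s^2)
}

#' Generate a synthetic observation set with known ground truth
#'
#' Emulates a recorded data set of per-posture rest-to-rest reaching
#' trials: for every task the bar problem is solved under the true weight
#' vector; each trial then jitters the endpoint on the bar (Gaussian, with
#' anisotropic x/z SDs), warps the nominal fingertip path toward the
#' jittered endpoint with a quintic ramp (or optionally re-solves a
#' fixed-endpoint problem), superimposes a smooth path perturbation built
#' from the first three sine half-waves (vanishing at both endpoints), and
#' rescales the duration. The trial-averaged, time-normalized trajectory
#' is stored as the per-posture reference, and the generating weights
#' travel along as ground truth.
#'
#' @param true_weights a [cost_weights()] object (the ground truth).
#' @param tasks list of bar [task_spec()]s (e.g. [default_postures()]).
#' @param noise a [noise_model()].
#' @param n_trials trials per posture.
#' @param params an [arm_params()] object.
#' @param options a [solver_options()] for the nominal solves.
#' @param resolve_trials if `TRUE`, each jittered endpoint is re-solved as
#'   a fixed-endpoint problem (slower, dynamically consistent per trial);
#'   by default trials are path-warps of the nominal solution.
#' @return an [observation_set()]; its `truth` field records the weights,
#'   the nominal solutions and the generator settings.
#' @export
generate_observations <- function(true_weights, tasks, noise = noise_model(),
                                  n_trials = 20, params,
                                  options = solver_options(nodes = 24),
                                  resolve_trials = FALSE) {
  stopifnot(n_trials >= 1, inherits(noise, "noise_model"))
  postures <- list()
  nominals <- list()
  with_seed(noise$seed, {
    for (ti in seq_along(tasks)) {
      task <- tasks[[ti]]
      nm <- if (!is.null(task$label)) task$label else paste0("P", ti)
      nominal <- solve_ocp(task, true_weights, params, options)
      if (nominal$status != "success")
        stop("nominal solve failed for posture ", nm)
      nominals[[nm]] <- nominal
      tr0 <- nominal$trajectory
      n <- nrow(tr0$hand$p)
      s <- seq(0, 1, length.out = n)
      rmp <- .quintic_ramp(s)
      trials <- vector("list", n_trials)
      ends <- matrix(0, n_trials, 2)
      for (k in seq_len(n_trials)) {
        dx <- stats::rnorm(1, 0, noise$endpoint_sd_x)
        dz <- stats::rnorm(1, 0, noise$endpoint_sd_z)
        Tk <- task$T * max(0.5, 1 + stats::rnorm(1, 0, noise$duration_cv))
        base <- if (resolve_trials) {
          tkk <- task_spec(task$q0,
                           point_target(c(tr0$hand$p[n, 1] + dx,
                                          nominal$z_f + dz)), Tk)
          oo <- options
          oo$init <- list(coefs = nominal$coefs)
          solve_ocp(tkk, true_weights, params, oo)$trajectory
        } else NULL
        if (is.null(base)) {
          # warp: translate the nominal path toward the jittered endpoint
          sc <- task$T / Tk
          p <- tr0$hand$p + rmp$d0 %o% c(dx, dz)
          v <- tr0$hand$v * sc + (rmp$d1 / Tk) %o% c(dx, dz)
          a <- tr0$hand$a * sc^2 + (rmp$d2 / Tk^2) %o% c(dx, dz)
          j <- tr0$hand$j * sc^3 + (rmp$d3 / Tk^3) %o% c(dx, dz)
        } else {
          p <- base$hand$p; v <- base$hand$v; a <- base$hand$a; j <- base$hand$j
        }
        if (noise$kinematic_sd > 0) {
          for (cc in 1:2) {
            am <- stats::rnorm(3, 0, noise$kinematic_sd) / (1:3)
            for (m in 1:3) {
              w <- m * pi
              p[, cc] <- p[, cc] + am[m] * sin(w * s)
              v[, cc] <- v[, cc] + am[m] * w * cos(w * s) / Tk
              a[, cc] <- a[, cc] - am[m] * w^2 * sin(w * s) / Tk^2
              j[, cc] <- j[, cc] - am[m] * w^3 * cos(w * s) / Tk^3
            }
          }
        }
        trials[[k]] <- .traj_from_hand_analytic(s * Tk, p, v, a, j, params)
        ends[k, ] <- p[n, ]
      }
      # trial-averaged, time-normalized reference
      Tbar <- mean(vapply(trials, function(tr) tr$T, numeric(1)))
      pm <- Reduce(`+`, lapply(trials, function(tr) tr$hand$p)) / n_trials
      vm <- Reduce(`+`, lapply(trials, function(tr) tr$hand$v * tr$T / Tbar)) /
        n_trials
      am <- Reduce(`+`, lapply(trials,
                               function(tr) tr$hand$a * (tr$T / Tbar)^2)) /
        n_trials
      jm <- Reduce(`+`, lapply(trials,
                               function(tr) tr$hand$j * (tr$T / Tbar)^3)) /
        n_trials
      reference <- .traj_from_hand_analytic(s * Tbar, pm, vm, am, jm, params)
      postures[[nm]] <- list(task = task, reference = reference,
                             trials = trials)
    }
  })
  observation_set(postures,
                  truth = list(weights = true_weights, nominal = nominals,
                               noise = noise, n_trials = n_trials))
}

#' Simulate the full experimental protocol under candidate models
#'
#' Crosses planning models (weight vectors) with subjects (anthropometric
#' parameter sets) and tasks, solves every cell, and tabulates the
#' kinematic summary of each predicted movement - the simulation-side
#' counterpart of a group motion analysis.
#'
#' @param weight_sets named list of [cost_weights()].
#' @param subjects list of [arm_params()] (one per simulated subject).
#' @param tasks list of [task_spec()]s, or a function of the subject's
#'   `arm_params` returning such a list (so bar distances scale with each
#'   subject's arm).
#' @param options a [solver_options()].
#' @return data.frame with one row per model x subject x task: `z_f`,
#'   `cost`, `ok`, and the [summarize_trajectory()] fields.
#' @export
simulate_protocol <- function(weight_sets, subjects, tasks,
                              options = solver_options(nodes = 24)) {
  stopifnot(length(weight_sets) >= 1, length(subjects) >= 1)
  rows <- list()
  for (mi in seq_along(weight_sets)) {
    for (si in seq_along(subjects)) {
      par_s <- subjects[[si]]
      task_list <- if (is.function(tasks)) tasks(par_s) else tasks
      for (ti in seq_along(task_list)) {
        task <- task_list[[ti]]
        lab <- if (!is.null(task$label)) task$label else paste0("T", ti)
        sol <- tryCatch(solve_ocp(task, weight_sets[[mi]], par_s, options),
                        error = function(e) NULL)
        okc <- !is.null(sol) && sol$status == "success"
        base <- data.frame(model = names(weight_sets)[mi], subject = si,
                           posture = lab, ok = okc,
                           z_f = if (okc) sol$z_f else NA_real_,
                           cost = if (okc) sol$cost else NA_real_)
        rows[[length(rows) + 1]] <- if (okc)
          cbind(base,
                as.data.frame(summarize_trajectory(sol$trajectory, task,
                                                   par_s)))
        else base
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(c("MD", "PV", "MV_vel", "TPV", "shape_index", "CD", "RP",
                      "MV_angle", "sIPC", "coupling_R2", "constant_error",
                      "variable_error", "CI"), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r
  }))
  rownames(out) <- NULL
  out
}
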