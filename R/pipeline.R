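#' Hybrid energy + joint-smoothness cost preset
#'
#' The composite cost identified as the best group-level account of
#' reaching-to-a-bar behavior: absolute-work energy combined with angular
#' acceleration at a raw weight ratio of 10:1 (energy:acceleration), the
#' other components zero.
#'
#' @param s re-scaling vector (see [compute_rescaling()]).
#' @param ratio energy : angle-acceleration raw weight ratio.
#' @return a [cost_weights()] object anchored at angle acceleration.
#' @export
hybrid_weights <- function(s = rep(1, 8), ratio = 10) {
  cost_weights(c(angle_accel = 1, energy = ratio), s, "angle_accel")
}

#' Point-versus-bar cost discriminability demo
#'
#' Reproduces the proof-of-concept comparison between the hand-jerk and
#' torque-change models: for several starting points, the two costs'
#' optimal fingertip paths are computed both toward a point target and
#' toward a bar, and the area enclosed between the pair of paths is
#' measured. Toward a point the two models predict nearly the same path;
#' the redundant bar target lets their predictions diverge (they choose
#' different endpoints), so the bar areas are systematically larger - the
#' task-design argument for using a redundant target to tell cost
#' functions apart. Movements are simulated in the horizontal plane
#' (gravity-free), as in classical point-to-point reaching studies.
#'
#' @param params an [arm_params()] object; its `g` is overridden to 0.
#' @param n_starts number of starting points (default 6).
#' @param options a [solver_options()].
#' @param seed seed for the Monte-Carlo area estimates.
#' @return list with `mean_area_bar`, `mean_area_point` (m^2) and a
#'   per-start data.frame `detail`.
#' @export
run_fig1_demo <- function(params = arm_params(), n_starts = 6,
                          options = solver_options(nodes = 24),
                          seed = 1L) {
  params$g <- 0  # horizontal plane
  d <- 0.85 * params$L
  ang <- seq(-50, 50, length.out = n_starts) * pi / 180
  r0 <- 0.55 * params$L
  w_hj <- cost_weights(c(hand_jerk = 1))
  w_tc <- cost_weights(c(torque_change = 1))
  rows <- NULL
  for (i in seq_len(n_starts)) {
    p0 <- r0 * c(cos(ang[i]), sin(ang[i]))
    q0 <- inverse_kinematics(p0, params)
    tk_bar <- task_spec(q0, bar_target(d), 0.7, paste0("S", i))
    tk_pt <- task_spec(q0, point_target(c(d, p0[2])), 0.7, paste0("S", i))
    s_hj_b <- solve_ocp(tk_bar, w_hj, params, options)
    s_tc_b <- solve_ocp(tk_bar, w_tc, params, options)
    s_hj_p <- solve_ocp(tk_pt, w_hj, params, options)
    s_tc_p <- solve_ocp(tk_pt, w_tc, params, options)
    # bar endpoints differ between the two models: close the region along
    # the bar itself by appending the segment between the two endpoints
    pa <- s_hj_b$trajectory$hand$p
    pb <- s_tc_b$trajectory$hand$p
    zseg <- seq(pa[nrow(pa), 2], pb[nrow(pb), 2], length.out = 20)
    pa_closed <- rbind(pa, cbind(rep(d, 20), zseg))
    area_bar <- area_between_paths(pa_closed, pb, seed = seed + i)
    area_pt <- area_between_paths(s_hj_p$trajectory$hand$p,
                                  s_tc_p$trajectory$hand$p, seed = seed + i)
    rows <- rbind(rows, data.frame(
      start = i, x0 = p0[1], z0 = p0[2],
      area_bar = as.numeric(area_bar), area_point = as.numeric(area_pt),
      zf_hand_jerk = s_hj_b$z_f, zf_torque_change = s_tc_b$z_f))
  }
  list(mean_area_bar = mean(rows$area_bar),
       mean_area_point = mean(rows$area_point),
       detail = rows)
}

# ---- on-disk interchange ------------------------------------------------

#' Write / read an observation directory
#'
#' Serializes an [observation_set()] as plain-text artifacts: one CSV per
#' trial and per reference (columns
#' `t,q1,q2,qd1,qd2,tau1,tau2,u1,u2,x,z`), one YAML task description per
#' posture, and a ground-truth JSON when present. The directory round-trips
#' through [read_observation_dir()].
#'
#' @param obs an [observation_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_observation_dir <- function(obs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(obs$postures)) {
    ps <- obs$postures[[nm]]
    yaml::write_yaml(.task_to_list(ps$task),
                     file.path(dir, paste0(nm, "_task.yaml")))
    utils::write.csv(.traj_to_df(ps$reference),
                     file.path(dir, paste0(nm, "_reference.csv")),
                     row.names = FALSE)
    for (k in seq_along(ps$trials))
      utils::write.csv(.traj_to_df(ps$trials[[k]]),
                       file.path(dir, sprintf("%s_trial%02d.csv", nm, k)),
                       row.names = FALSE)
  }
  if (!is.null(obs$truth))
    jsonlite::write_json(
      list(alpha = as.list(obs$truth$weights$alpha),
           s = as.list(obs$truth$weights$s),
           anchor = cost_names()[obs$truth$weights$anchor],
           noise = unclass(obs$truth$noise),
           n_trials = obs$truth$n_trials),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_observation_dir
#' @param params an [arm_params()] object used to rebuild trajectories.
#' @export
read_observation_dir <- function(dir, params) {
  task_files <- list.files(dir, "_task\\.yaml$", full.names = TRUE)
  stopifnot(length(task_files) >= 1)
  postures <- list()
  for (tf in task_files) {
    nm <- sub("_task\\.yaml$", "", basename(tf))
    task <- .task_from_list(yaml::read_yaml(tf))
    ref <- .traj_from_df(
      utils::read.csv(file.path(dir, paste0(nm, "_reference.csv"))), params)
    trial_files <- list.files(dir, paste0("^", nm, "_trial[0-9]+\\.csv$"),
                              full.names = TRUE)
    trials <- lapply(trial_files,
                     function(f) .traj_from_df(utils::read.csv(f), params))
    postures[[nm]] <- list(task = task, reference = ref, trials = trials)
  }
  truth <- NULL
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) {
    tj <- jsonlite::read_json(gt, simplifyVector = TRUE)
    truth <- list(weights = cost_weights(unlist(tj$alpha), unlist(tj$s),
                                         tj$anchor))
  }
  observation_set(postures, truth)
}

.traj_to_df <- function(tr) {
  data.frame(t = tr$t, q1 = tr$q[, 1], q2 = tr$q[, 2],
             qd1 = tr$qd[, 1], qd2 = tr$qd[, 2],
             tau1 = tr$tau[, 1], tau2 = tr$tau[, 2],
             u1 = tr$u[, 1], u2 = tr$u[, 2],
             x = tr$hand$p[, 1], z = tr$hand$p[, 2])
}

.traj_from_df <- function(df, params) {
  reach_trajectory(df$t, cbind(df$q1, df$q2), params = params)
}

.task_to_list <- function(task) {
  list(q0 = as.numeric(task$q0), T = task$T, label = task$label,
       target = if (task$target$type == "bar")
         list(type = "bar", d = task$target$d)
       else list(type = "point", p = as.numeric(task$target$p)))
}

.task_from_list <- function(x) {
  tg <- if (x$target$type == "bar") bar_target(x$target$d)
        else point_target(unlist(x$target$p))
  task_spec(unlist(x$q0), tg, x$T, x$label)
}

#' Build arm parameters from a configuration list
#'
#' Accepts the `arm:` block of a YAML/JSON run configuration (fields named
#' as in [arm_params()], all optional; `B` may be a 4-element row-major
#' vector) and returns the corresponding parameter object.
#'
#' @param cfg a named list (possibly empty) of overrides.
#' @return an [arm_params()] object.
#' @export
arm_params_from_config <- function(cfg = list()) {
  if (!is.null(cfg$B)) cfg$B <- matrix(unlist(cfg$B), 2, 2, byrow = TRUE)
  known <- intersect(names(cfg), names(formals(arm_params)))
  do.call(arm_params, cfg[known])
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands used by the `inst/cli/reachioc.R`
#' script: `generate` (synthetic observation directory), `analyze`
#' (kinematic summary table of an observation directory), `fit` (inverse
#' optimal control on an observation directory), `sweep-endpoint`
#' (cost-versus-endpoint profile along the bar) and `demo-fig1` (the
#' point-versus-bar discriminability demo). Every run writes a manifest
#' (config hash, seed, package version) next to its outputs, making reruns
#' reproducible.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first, then `--config path`, `--out dir`, `--seed n`, `--budget n`,
#'   `--nodes n`).
#' @return exit status, invisibly (0 on success).
#' @export
run_command <- function(argv) {
  if (length(argv) < 1) {
    message("usage: reachioc <generate|analyze|fit|sweep-endpoint|demo-fig1> ",
            "[--config f] [--out dir] [--seed n] [--budget n] [--nodes n]")
    return(invisible(1L))
  }
  cmd <- argv[1]
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
  }
  out_dir <- opt("--out", "reachioc_out")
  seed <- as.integer(opt("--seed", "1"))
  nodes <- as.integer(opt("--nodes", "24"))
  cfg <- list()
  cfg_file <- opt("--config")
  if (!is.null(cfg_file)) cfg <- yaml::read_yaml(cfg_file)
  params <- arm_params_from_config(cfg$arm %||% list())
  options <- solver_options(nodes = nodes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(command = cmd, seed = seed, nodes = nodes,
                   config = if (is.null(cfg_file)) NULL else
                     unname(tools::md5sum(cfg_file)),
                   package = as.character(utils::packageVersion("reachioc")))
  status <- 0L
  res <- tryCatch({
    switch(cmd,
      "generate" = {
        tasks <- if (!is.null(cfg$tasks))
          lapply(cfg$tasks, .task_from_list) else default_postures(params)
        s <- compute_rescaling(tasks, params, options)
        w <- .weights_from_config(cfg$weights, s)
        nm <- do.call(noise_model,
                      c(cfg$noise %||% list(), list(seed = seed)))
        obs <- generate_observations(w, tasks, nm,
                                     n_trials = cfg$n_trials %||% 20,
                                     params = params, options = options)
        write_observation_dir(obs, out_dir)
      },
      "analyze" = {
        src <- cfg$observations %||% opt("--obs", out_dir)
        obs <- read_observation_dir(src, params)
        tab <- NULL
        for (nm in names(obs$postures)) {
          ps <- obs$postures[[nm]]
          sm <- summarize_trajectory(ps$reference, ps$task, params,
                                     ps$trials)
          tab <- rbind(tab, cbind(posture = nm, as.data.frame(sm)))
        }
        utils::write.csv(tab, file.path(out_dir, "summary.csv"),
                         row.names = FALSE)
        tab
      },
      "fit" = {
        src <- cfg$observations %||% opt("--obs", out_dir)
        obs <- read_observation_dir(src, params)
        cfgi <- inverse_config(budget = as.integer(opt("--budget", "150")),
                               seed = seed)
        fit <- fit_weights(obs, cfgi, params, options)
        jsonlite::write_json(
          list(alpha = as.list(fit$weights$alpha),
               alpha_normalized = as.list(fit$alpha_normalized),
               contributions = as.list(fit$contributions),
               phi = fit$phi, phi_by_posture = as.list(fit$phi_by_posture),
               best_restart = fit$best_restart),
          file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
        for (nm in names(fit$solutions))
          utils::write.csv(
            cbind(.traj_to_df(fit$solutions[[nm]]$trajectory),
                  ref_x = obs$postures[[nm]]$reference$hand$p[, 1],
                  ref_z = obs$postures[[nm]]$reference$hand$p[, 2]),
            file.path(out_dir, paste0(nm, "_overlay.csv")),
            row.names = FALSE)
        fit
      },
      "sweep-endpoint" = {
        tasks <- if (!is.null(cfg$tasks))
          lapply(cfg$tasks, .task_from_list) else default_postures(params)
        s <- compute_rescaling(tasks[1], params, options)
        w <- .weights_from_config(cfg$weights, s)
        prof <- endpoint_cost_profile(tasks[[1]], w, params,
                                      spacing = cfg$spacing %||% 0.03,
                                      options = options)
        utils::write.csv(prof, file.path(out_dir, "endpoint_profile.csv"),
                         row.names = FALSE)
        prof
      },
      "demo-fig1" = {
        demo <- run_fig1_demo(params, options = options, seed = seed)
        jsonlite::write_json(
          list(mean_area_bar = demo$mean_area_bar,
               mean_area_point = demo$mean_area_point),
          file.path(out_dir, "fig1_demo.json"), auto_unbox = TRUE,
          digits = NA)
        message(sprintf("mean area: bar %.5f m^2, point %.5f m^2",
                        demo$mean_area_bar, demo$mean_area_point))
        demo
      },
      stop("unknown subcommand: ", cmd))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    status <<- 1L
    NULL
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.weights_from_config <- function(wcfg, s) {
  if (is.null(wcfg)) return(hybrid_weights(s))
  if (is.character(wcfg) && length(wcfg) == 1) {
    if (wcfg == "hybrid") return(hybrid_weights(s))
    return(cost_weights(stats::setNames(1, wcfg), s, wcfg))
  }
  cost_weights(unlist(wcfg), s)
}
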