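# Run code with a transient RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Signed index of path curvature (sIPC)
#'
#' Maximum deviation of a planar path from the chord connecting its
#' endpoints, divided by the chord length; positive when the
#' maximum-deviation point lies above the chord line (globally concave
#' path), negative below (convex). A semicircle above its chord scores
#' +0.5.
#'
#' @param p n x 2 matrix of path points (x, z).
#' @return scalar in (-1, 1) for sane reaching paths.
#' @export
sipc <- function(p) {
  p <- .as_qmat(p)
  n <- nrow(p)
  chord <- p[n, ] - p[1, ]
  len <- sqrt(sum(chord^2))
  if (len < 1e-9) stop("degenerate chord (start = end); sIPC undefined")
  u <- chord / len
  rel <- sweep(p, 2, p[1, ])
  dev <- rel[, 2] * u[1] - rel[, 1] * u[2]  # signed perpendicular distance
  i <- which.max(abs(dev))
  d <- abs(dev[i]) / len
  # sign: "above the chord line" is positive; for (near-)vertical chords
  # fall back to the left-of-direction convention
  sgn <- if (abs(chord[1]) > 1e-9) {
    zline <- p[1, 2] + (p[i, 1] - p[1, 1]) * chord[2] / chord[1]
    sign(p[i, 2] - zline)
  } else sign(dev[i])
  if (sgn == 0) 0 else sgn * d
}

#' Preprocess a raw recorded trajectory
#'
#' Mirrors a standard motion-analysis chain for sampled reaching data:
#' zero-phase low-pass filtering (5th-order Butterworth applied
#' forward-backward, 10 Hz cutoff by default), movement segmentation at 5%
#' of peak tangential speed (first upward crossing before the global peak
#' to last downward crossing after it), and time normalization of the
#' movement window to exactly 200 samples by cubic-spline interpolation.
#'
#' @param raw data.frame with column `t` (s, uniformly sampled) plus either
#'   fingertip columns `x`, `z` (m) or joint columns `q1`, `q2` (rad).
#' @param params an [arm_params()] object (used to convert between joint
#'   and fingertip coordinates).
#' @param fs sampling frequency (Hz); inferred from `t` when `NULL`.
#' @param cutoff filter cutoff (Hz).
#' @param order Butterworth order (effective order doubles under
#'   forward-backward filtering).
#' @param threshold onset/offset threshold as a fraction of peak speed.
#' @param n_out samples of the normalized output window.
#' @return a [reach_trajectory()] on the trimmed, normalized window, with
#'   attributes `MD` (movement duration, s), `cd_raw` (curvilinear distance
#'   integrated on the filtered pre-resampling grid, m), `onset`, `offset`
#'   (s, in the raw time base) and `peak_speed` (m/s).
#' @export
preprocess <- function(raw, params, fs = NULL, cutoff = 10, order = 5,
                       threshold = 0.05, n_out = 200) {
  raw <- as.data.frame(raw)
  stopifnot("t" %in% names(raw), nrow(raw) >= 20)
  t <- raw$t
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  stopifnot(fs > 0)
  if (all(c("x", "z") %in% names(raw))) {
    p <- cbind(raw$x, raw$z)
  } else if (all(c("q1", "q2") %in% names(raw))) {
    p <- forward_kinematics(cbind(raw$q1, raw$q2), params)$p
  } else stop("raw data must contain columns x,z or q1,q2")
  bf <- signal::butter(order, min(cutoff / (fs / 2), 0.99))
  # reflect the record at both ends before zero-phase filtering, so filter
  # start-up transients fall outside the retained window
  npad <- min(nrow(p) - 1, ceiling(3 * fs / cutoff))
  pf <- apply(p, 2, function(y) {
    ypad <- c(2 * y[1] - rev(y[2:(npad + 1)]), y,
              2 * y[length(y)] - rev(y[length(y) - seq_len(npad)]))
    m <- mean(ypad)  # center so start-up transients act on a zero-mean signal
    signal::filtfilt(bf, ypad - m)[npad + seq_along(y)] + m
  })
  v <- fd_derivative(t, pf)
  speed <- sqrt(rowSums(v^2))
  pv <- max(speed)
  if (pv <= 1e-9) stop("flat signal: zero peak speed; cannot segment")
  ipk <- which.max(speed)
  # movement window: the contiguous above-threshold run containing the
  # global speed peak (threshold crossings caused by pre/post-movement
  # noise or tremor are thereby excluded)
  above <- speed > threshold * pv
  below_pre <- which(!above[seq_len(ipk)])
  onset <- if (length(below_pre)) max(below_pre) + 1L else 1L
  below_post <- which(!above[ipk:length(speed)])
  offset <- if (length(below_post)) ipk + min(below_post) - 2L
            else length(speed)
  if (is.na(onset) || offset - onset + 1 < 5)
    stop("movement window shorter than 5 samples")
  idx <- onset:offset
  cd_raw <- sum(.trapz_weights(t[idx]) * speed[idx])
  # time-normalized resampling of the window
  tw <- t[idx]
  tt <- seq(tw[1], tw[length(tw)], length.out = n_out)
  pr <- apply(pf[idx, , drop = FALSE], 2,
              function(y) stats::spline(tw, y, xout = tt)$y)
  out <- trajectory_from_hand(tt - tt[1], pr, params)
  attr(out, "MD") <- tw[length(tw)] - tw[1]
  attr(out, "cd_raw") <- cd_raw
  attr(out, "onset") <- tw[1]
  attr(out, "offset") <- tw[length(tw)]
  attr(out, "peak_speed") <- pv
  out
}

#' Scalar kinematic summary of a reaching movement
#'
#' Computes the standard movement features used to compare reaching models
#' with data: movement duration (MD), peak and mean tangential speed (PV,
#' MV_vel), relative time to peak speed (TPV), the speed-shape index
#' PV/MV_vel (1.875 for a minimum-jerk quintic), curvilinear distance (CD),
#' the reached point normalized by arm length (RP), the movement-vector
#' angle (MV_angle, degrees counterclockwise from horizontal), the signed
#' index of path curvature (sIPC), shoulder-elbow coupling (determination
#' coefficient of a linear fit of elbow on shoulder angle), and - when
#' repeated trials are supplied - endpoint constant/variable errors and the
#' consistency index CI (endpoint SD along the bar divided by the length of
#' the reachable region).
#'
#' @param traj a [reach_trajectory()] (preprocessed or solver output).
#' @param task optional [task_spec()]; needed for the constant error and CI
#'   (bar geometry).
#' @param params optional [arm_params()]; needed for RP and CI.
#' @param trials optional list of `reach_trajectory` trials of the same
#'   movement, for the dispersion measures.
#' @return an object of class `kinematic_summary` (a named list);
#'   `as.data.frame()` turns it into a one-row data.frame.
#' @export
summarize_trajectory <- function(traj, task = NULL, params = NULL,
                                 trials = NULL) {
  sp <- hand_speed(traj)
  n <- length(sp)
  MD <- traj$T
  PV <- max(sp)
  MV_vel <- sum(traj$quad_w * sp) / MD
  ipk <- which.max(sp)
  p <- traj$hand$p
  chord <- p[n, ] - p[1, ]
  cd <- attr(traj, "cd_raw")
  if (is.null(cd)) cd <- sum(traj$quad_w * sp)
  s_ipc <- if (sqrt(sum(chord^2)) > 1e-9) sipc(p) else NA_real_
  r2 <- {
    fit <- stats::lm.fit(cbind(1, traj$q[, 1]), traj$q[, 2])
     1 - sum(fit$residuals^2) / max(sum((traj$q[, 2] - mean(traj$q[, 2]))^2),
                                   1e-300)
  }
  out <- list(
    MD = MD, PV = PV, MV_vel = MV_vel,
    TPV = (traj$t[ipk] - traj$t[1]) / MD,
    shape_index = PV / MV_vel,
    CD = cd,
    RP = if (!is.null(params)) p[n, 2] / params$L else NA_real_,
    MV_angle = atan2(chord[2], chord[1]) * 180 / pi,
    sIPC = s_ipc,
    coupling_R2 = min(max(r2, 0), 1),
    constant_error = NA_real_, variable_error = NA_real_, CI = NA_real_)
  if (!is.null(task) && task$target$type == "bar")
    out$constant_error <- abs(p[n, 1] - task$target$d)
  if (!is.null(trials) && length(trials) >= 2) {
    ends <- t(vapply(trials, function(tr) tr$hand$p[nrow(tr$hand$p), ],
                     numeric(2)))
    ctr <- colMeans(ends)
    out$variable_error <- stats::sd(sqrt(rowSums(sweep(ends, 2, ctr)^2)))
    if (!is.null(task) && task$target$type == "bar" && !is.null(params)) {
      zr <- .reach_halfspan(params, task$target$d)
      out$CI <- stats::sd(ends[, 2]) / (2 * zr)
    }
  }
  structure(out, class = "kinematic_summary")
}

#' @export
as.data.frame.kinematic_summary <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf(paste0("movement summary: MD=%.3f s, PV=%.3f m/s, ",
                     "shape=%.3f, TPV=%.2f, CD=%.3f m\n"),
              x$MD, x$PV, x$shape_index, x$TPV, x$CD))
  cat(sprintf("  RP=%.3f, MV=%.1f deg, sIPC=%+.3f, coupling R2=%.3f\n",
              x$RP, x$MV_angle, x$sIPC, x$coupling_R2))
  if (!is.na(x$variable_error))
    cat(sprintf("  endpoint: var err=%.4f m, CI=%.4f\n",
                x$variable_error, x$CI))
  invisible(x)
}

#' Monte-Carlo area between two paths
#'
#' Unbiased Monte-Carlo estimate of the area enclosed between two planar
#' paths sharing (approximately) their endpoints: uniform points are drawn
#' in the joint bounding box and tested against the closed region formed by
#' the first path followed by the reversed second path (even-odd rule, so
#' regions where the paths swap sides both count positively).
#'
#' @param pathA,pathB n x 2 matrices of path points; endpoints must agree
#'   within 1 cm (the region is closed with straight segments).
#' @param n_samples number of Monte-Carlo points (>= 1000).
#' @param seed optional seed making the estimate reproducible without
#'   touching the caller's RNG stream.
#' @return estimated area (m^2), with attributes `se` (standard error) and
#'   `n` (samples used).
#' @export
area_between_paths <- function(pathA, pathB, n_samples = 1e5, seed = NULL) {
  pathA <- .as_qmat(pathA); pathB <- .as_qmat(pathB)
  stopifnot(n_samples >= 1000)
  na <- nrow(pathA); nb <- nrow(pathB)
  if (max(sqrt(sum((pathA[1, ] - pathB[1, ])^2)),
          sqrt(sum((pathA[na, ] - pathB[nb, ])^2))) > 0.01)
    stop("path endpoints differ by more than 1 cm; cannot close the region")
  if (na == nb && max(abs(pathA - pathB)) < 1e-12)
    return(structure(0, se = 0, n = n_samples))
  poly <- rbind(pathA, pathB[nb:1, ])
  xr <- range(poly[, 1]); zr <- range(poly[, 2])
  box <- diff(xr) * diff(zr)
  if (box <= 0) return(structure(0, se = 0, n = n_samples))
  inside <- with_seed(seed, {
    pts <- cbind(stats::runif(n_samples, xr[1], xr[2]),
                 stats::runif(n_samples, zr[1], zr[2]))
    mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
  })
  phat <- mean(inside)
  structure(box * phat,
            se = box * sqrt(phat * (1 - phat) / n_samples),
            n = n_samples)
}
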