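test_that("noise-free trials replicate the nominal solution exactly", {
  obs <- fx_obs_accel()
  for (nm in names(obs$postures)) {
    ps <- obs$postures[[nm]]
    expect_lt(max(abs(ps$trials[[1]]$hand$p - ps$reference$hand$p)), 1e-12)
    expect_lt(max(abs(ps$trials[[2]]$hand$p - ps$trials[[1]]$hand$p)), 1e-12)
  }
  sm <- summarize_trajectory(obs$postures$P2$reference,
                             obs$postures$P2$task, fx_params(),
                             obs$postures$P2$trials)
  expect_equal(sm$variable_error, 0, tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  par <- fx_params()
  s <- fx_rescaling()
  w <- cost_weights(c(angle_accel = 1), s)
  tk <- fx_tasks()["P2"]
  nz <- noise_model(0.02, 0.01, 0.003, 0.08, seed = 5)
  o1 <- generate_observations(w, tk, nz, 3, par, fx_opts())
  o2 <- generate_observations(w, tk, nz, 3, par, fx_opts())
  expect_identical(o1$postures$P2$trials[[2]]$q,
                   o2$postures$P2$trials[[2]]$q)
  o3 <- generate_observations(w, tk, noise_model(0.02, 0.01, 0.003, 0.08,
                                                 seed = 6), 3, par, fx_opts())
  expect_gt(max(abs(o1$postures$P2$trials[[2]]$q -
                      o3$postures$P2$trials[[2]]$q)), 1e-6)
})

test_that("endpoint scatter follows the prescribed anisotropic SDs", {
  par <- fx_params()
  s <- fx_rescaling()
  w <- cost_weights(c(angle_accel = 1), s)
  tk <- fx_tasks()["P2"]
  obs <- generate_observations(w, tk, noise_model(0.03, 0.01, 0, 0,
                                                  seed = 21),
                               n_trials = 200, params = par,
                               options = fx_opts())
  ends <- t(sapply(obs$postures$P2$trials,
                   function(tr) tr$hand$p[nrow(tr$hand$p), ]))
  expect_lt(abs(sd(ends[, 2]) - 0.03) / 0.03, 0.15)
  expect_lt(abs(sd(ends[, 1]) - 0.01) / 0.01, 0.15)
  # consistency index: endpoint SD over reachable-region length
  sm <- summarize_trajectory(obs$postures$P2$reference, obs$postures$P2$task,
                             par, obs$postures$P2$trials)
  zr <- sqrt(par$L^2 - obs$postures$P2$task$target$d^2)
  expect_equal(sm$CI, sd(ends[, 2]) / (2 * zr), tolerance = 1e-9)
})

test_that("noisy trials keep approximate rest-to-rest boundary conditions", {
  par <- fx_params()
  s <- fx_rescaling()
  w <- cost_weights(c(angle_accel = 1), s)
  obs <- generate_observations(w, fx_tasks()["P3"],
                               noise_model(0.03, 0.01, 0.005, 0.1, seed = 2),
                               n_trials = 4, params = par,
                               options = fx_opts())
  for (tr in obs$postures$P3$trials) {
    n <- nrow(tr$hand$p)
    expect_lt(max(abs(tr$hand$p[n, 1] -
                        obs$postures$P3$task$target$d)), 0.05)
    # endpoint positions exact; endpoint speeds small relative to the peak
    # (the sine perturbation basis vanishes at the endpoints in position,
    # leaving only a small residual velocity there)
    sp <- hand_speed(tr)
    expect_lt(sp[1], 0.2 * max(sp))
    expect_lt(sp[n], 0.2 * max(sp))
  }
})

test_that("simulate_protocol tabulates joint-space-straight models correctly", {
  par <- fx_params()
  subj <- list(par, arm_params(mass = 60, height = 1.65))
  models <- list(angle_accel = cost_weights(c(angle_accel = 1)),
                 hand_jerk = cost_weights(c(hand_jerk = 1)))
  tab <- simulate_protocol(models, subj,
                           function(p) default_postures(p)[c("P2", "P3")],
                           fx_opts())
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_true(all(tab$ok))
  # joint-smoothness models produce straight joint-space paths
  acc <- tab[tab$model == "angle_accel", ]
  expect_true(all(acc$coupling_R2 > 0.99))
  # hand-jerk bar movements are horizontal
  hj <- tab[tab$model == "hand_jerk", ]
  expect_true(all(abs(hj$MV_angle) < 2))
  expect_true(all(abs(hj$shape_index - 1.875) < 0.03))
})
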