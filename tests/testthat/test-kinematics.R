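test_that("preprocess recovers a noisy quintic movement", {
  par <- fx_params()
  T <- 0.62
  mj <- min_jerk_analytic(c(0.30, 0.10), c(0.60, 0.25), T, 63)
  set.seed(3)
  pad <- 20
  raw <- data.frame(
    t = c(seq(-0.2, -0.01, by = 0.01), mj$t, T + seq(0.01, 0.2, by = 0.01)),
    x = c(rep(0.30, pad), mj$hand$p[, 1], rep(0.60, pad)),
    z = c(rep(0.10, pad), mj$hand$p[, 2], rep(0.25, pad)))
  raw$x <- raw$x + rnorm(nrow(raw), 0, 0.002)
  raw$z <- raw$z + rnorm(nrow(raw), 0, 0.002)
  tr <- preprocess(raw, par, fs = 100)
  expect_equal(length(tr$t), 200)
  # 5%-of-peak trimming of a quintic retains the central fraction of the
  # movement whose speed exceeds threshold: 30 s^2(1-s)^2 = 0.05 * 1.875
  sl <- uniroot(function(s) 30 * s^2 * (1 - s)^2 - 0.05 * 1.875,
                c(0, 0.5))$root
  expect_lt(abs(attr(tr, "MD") - (1 - 2 * sl) * T) / T, 0.05)
  # path geometry survives: straight, correct direction
  expect_lt(abs(sipc(tr$hand$p)), 0.02)
})

test_that("segmentation follows the 5% threshold on a clean profile", {
  par <- fx_params()
  # triangular speed profile: position = integral of triangle
  fs <- 100
  t <- seq(0, 1, by = 1 / fs)
  speed <- pmin(t, 1 - t)            # peaks at 0.5 m/s at t = 0.5
  x <- 0.3 + cumsum(speed) / fs
  raw <- data.frame(t = t, x = x, z = rep(0.1, length(t)))
  tr <- preprocess(raw, par, fs = fs, cutoff = 20)
  on <- attr(tr, "onset")
  expect_lt(abs(on - 0.05 / 2), 0.04)  # first sample with speed > 5% of peak
  expect_equal(length(tr$t), 200)
  expect_error(preprocess(data.frame(t = t, x = rep(0.4, length(t)),
                                     z = rep(0.1, length(t))), par, fs = fs),
               "flat|peak")
})

test_that("summary of the analytic minimum-jerk profile is exact", {
  par <- fx_params()
  mj <- min_jerk_analytic(c(0.30, 0.10), c(0.60, 0.10), 0.7, 201, par)
  sm <- summarize_trajectory(mj, params = par)
  expect_equal(sm$shape_index, 1.875, tolerance = 1e-3)
  expect_equal(sm$TPV, 0.5, tolerance = 1e-6)
  expect_equal(sm$sIPC, 0, tolerance = 1e-9)
  expect_equal(sm$CD, 0.30, tolerance = 1e-4)        # straight: CD = chord
  expect_equal(sm$MV_angle, 0, tolerance = 1e-6)
  expect_equal(sm$RP, 0.10 / par$L, tolerance = 1e-9)
})

test_that("sIPC signs semicircles and is antisymmetric under reflection", {
  th <- seq(0, pi, length.out = 200)
  semi <- cbind(0.5 - 0.5 * cos(th), 0.5 * sin(th))
  expect_equal(sipc(semi), 0.5, tolerance = 1e-3)
  expect_equal(sipc(cbind(semi[, 1], -semi[, 2])), -0.5, tolerance = 1e-3)
  # reflection about an arbitrary chord flips the sign exactly
  set.seed(8)
  for (i in 1:10) {
    s <- seq(0, 1, length.out = 50)
    p0 <- runif(2, -0.3, 0.3); p1 <- runif(2, 0.4, 0.8)
    dev <- sin(pi * s) * runif(1, -0.2, 0.2) +
      sin(2 * pi * s) * runif(1, -0.1, 0.1)
    u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    nrm <- c(-u[2], u[1])
    path <- cbind(p0[1] + (p1[1] - p0[1]) * s, p0[2] + (p1[2] - p0[2]) * s) +
      dev %o% nrm
    refl <- cbind(p0[1] + (p1[1] - p0[1]) * s, p0[2] + (p1[2] - p0[2]) * s) -
      dev %o% nrm
    expect_equal(sipc(path), -sipc(refl), tolerance = 1e-12)
  }
  expect_error(sipc(matrix(c(0.3, 0.3, 0.1, 0.1), 2, 2)), "degenerate")
})

test_that("path-geometry summaries are invariant to uniform time rescaling", {
  par <- fx_params()
  tr1 <- fx_curved_traj(par, T = 0.7)
  tr2 <- fx_curved_traj(par, T = 1.4)
  s1 <- summarize_trajectory(tr1, params = par)
  s2 <- summarize_trajectory(tr2, params = par)
  for (f in c("RP", "MV_angle", "sIPC", "CD", "coupling_R2", "TPV",
              "shape_index"))
    expect_equal(s1[[f]], s2[[f]], tolerance = 1e-8, label = f)
  expect_equal(s2$MD, 2 * s1$MD)
  expect_equal(s2$PV, s1$PV / 2, tolerance = 1e-8)
})

test_that("Monte-Carlo area: identity, unit square, and scaling law", {
  pa <- cbind(seq(0, 1, length.out = 50), 0)
  expect_equal(as.numeric(area_between_paths(pa, pa)), 0)
  expect_equal(attr(area_between_paths(pa, pa), "se"), 0)
  pb <- rbind(cbind(0, seq(0, 1, length.out = 20)),
              cbind(seq(0, 1, length.out = 20), 1),
              cbind(1, seq(1, 0, length.out = 20)))
  ar <- area_between_paths(pa, pb, 1e5, seed = 42)
  expect_equal(as.numeric(ar), 1, tolerance = 0.02)
  # standard error scales as 1/sqrt(n)
  th <- seq(0, pi, length.out = 60)
  arcA <- cbind(th / pi, 0.4 * sin(th))
  arcB <- cbind(th / pi, 0.15 * sin(th))
  se1 <- attr(area_between_paths(arcA, arcB, 4e4, seed = 1), "se")
  se2 <- attr(area_between_paths(arcA, arcB, 2e4, seed = 1), "se")
  expect_equal(se2 / se1, sqrt(2), tolerance = 0.1)
  expect_error(area_between_paths(arcA, arcB + 0.5, 1e4), "endpoints")
})

test_that("Monte-Carlo area agrees with the shoelace oracle", {
  set.seed(99)
  for (i in 1:20) {
    poly <- random_star_polygon(sample(6:16, 1))
    truth <- shoelace_area(poly)
    half <- floor(nrow(poly) / 2)
    pa <- poly[1:half, , drop = FALSE]
    pb <- poly[c(1, nrow(poly):half), , drop = FALSE]  # complementary arc
    ar <- area_between_paths(pa, pb, 2e4, seed = i)
    expect_lt(abs(as.numeric(ar) - truth), 3 * attr(ar, "se") + 1e-9)
  }
})
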