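test_that("pressure trace matches the ventilator contract", {
  geom <- scan_geometry()               # 500 frames @ 40 Hz
  vent <- quiet_vent()
  tr <- make_pressure(vent, geom)
  expect_equal(nrow(tr), 12.5 * 5000)   # duration * pressure rate
  expect_equal(max(tr$time_s) + 1 / 5000, 12.5)
  # noiseless plateau hits MIP and baseline hits PEEP exactly
  expect_equal(max(tr$pressure_cmH2O), vent$mip_cmH2O)
  expect_equal(min(tr$pressure_cmH2O), vent$peep_cmH2O)
  # attenuation scales the modulation amplitude only
  tr2 <- make_pressure(quiet_vent(attenuation = 0.5), geom)
  expect_equal(max(tr2$pressure_cmH2O),
               vent$peep_cmH2O + 0.5 * (vent$mip_cmH2O - vent$peep_cmH2O))
  expect_equal(min(tr2$pressure_cmH2O), vent$peep_cmH2O)
})

test_that("noiseless waveform is exactly periodic", {
  vent <- quiet_vent()
  t <- seq(0, 3, by = 1e-3)
  expect_equal(ventilator_waveform(t, vent),
               ventilator_waveform(t + 60 / vent$breaths_per_min, vent))
})

test_that("seeded noise is reproducible and has the stated scale", {
  geom <- scan_geometry(n_frames = 100)
  a <- make_pressure(ventilator_params(), geom, seed = 5)
  b <- make_pressure(ventilator_params(), geom, seed = 5)
  expect_identical(a, b)
  clean <- make_pressure(quiet_vent(), geom)
  resid <- a$pressure_cmH2O - clean$pressure_cmH2O
  expect_equal(sd(resid), 1.32, tolerance = 0.05)
})

test_that("ventilator parameter invariants are enforced", {
  expect_error(ventilator_params(mip_cmH2O = 4, peep_cmH2O = 5), "MIP")
  expect_error(ventilator_params(attenuation = 0))
  expect_error(ventilator_params(insp_fraction = 1))
})

test_that("analytic nCsC matches the finite-difference elasticity oracle", {
  # oracle: FD solution of u'' + u'/r - u/r^2 = 0 with traction BCs
  # frozen value computed with lame_fd_ncsc(8, 10, 500, 0.45): 1.714222
  expect_equal(analytic_ncsc(tube_model(8, 10, 500, 0.45)), 1.714222,
               tolerance = 1e-4)
  for (cfg in list(c(5, 6.25, 1000, 0.4), c(11, 13.75, 4000, 0.3),
                   c(8, 10, 2000, 0))) {
    tube <- tube_model(cfg[1], cfg[2], cfg[3], cfg[4])
    expect_equal(analytic_ncsc(tube),
                 lame_fd_ncsc(cfg[1], cfg[2], cfg[3], cfg[4]),
                 tolerance = 0.01)
  }
})

test_that("nCsC is dimensionless in size, linear in 1/E, monotone in wall", {
  base <- tube_model(8, 10, 800, 0.45)
  for (k in c(0.5, 2, 3.7)) {
    scaled <- tube_model(8 * k, 10 * k, 800, 0.45)
    expect_equal(analytic_ncsc(scaled), analytic_ncsc(base))
  }
  expect_equal(analytic_ncsc(tube_model(8, 10, 1600, 0.45)),
               analytic_ncsc(base) / 2)
  # thinner wall at fixed a -> more compliant; stiffer E -> less compliant
  walls <- sapply(c(12, 11, 10.5, 10.1), function(b)
    analytic_ncsc(tube_model(8, b, 800, 0.45)))
  expect_true(all(diff(walls) > 0))
  es <- sapply(c(500, 1000, 2000, 4000), function(E)
    analytic_ncsc(tube_model(8, 10, E, 0.45)))
  expect_true(all(diff(es) < 0))
  expect_error(tube_model(10, 8, 500, 0.45), "b > a")
})

test_that("simulated boundary at rest is the rest circle", {
  geom <- small_geom(n_frames = 5)
  tube <- test_tube()
  rest <- data.frame(time_s = seq(0, 0.2, by = 1 / 5000),
                     pressure_cmH2O = tube$rest_pressure_cmH2O)
  gt <- simulate_boundary(tube, rest, geom)
  expect_equal(unname(diff(range(gt$boundary_mm))), 0)
  expect_equal(gt$csa_mm2, rep(pi * 8^2, 5), tolerance = 1e-3)
})

test_that("ground-truth fields reproduce the linear response formula", {
  geom <- small_geom(n_frames = 260)
  # oracle: direct evaluation of the linear CSA(p) response. The
  # extrema-based estimate normalizes by the mid-range CSA, so it equals
  # s / (1 + s dp / 2) with s = nCsC/100 -- indistinguishable from the
  # analytic (rest-state derivative) value once the strain is small.
  meas_mid <- function(tube) {
    pr <- make_pressure(quiet_vent(), geom)
    gt <- simulate_boundary(tube, pr, geom)
    100 * (max(gt$csa_mm2) - min(gt$csa_mm2)) /
      ((max(gt$csa_mm2) + min(gt$csa_mm2)) / 2) / (18 - 5)
  }
  tube <- test_tube()
  s <- analytic_ncsc(tube) / 100
  expect_equal(meas_mid(tube), 100 * s / (1 + s * 13 / 2), tolerance = 1e-6)
  stiff <- test_tube(E = 8000)
  expect_equal(meas_mid(stiff), analytic_ncsc(stiff), tolerance = 0.01)
})

test_that("offset catheter produces the offset-circle radii and same CSA", {
  geom <- small_geom(n_frames = 2)
  tube <- test_tube()
  rest <- data.frame(time_s = seq(0, 0.1, by = 1 / 5000),
                     pressure_cmH2O = tube$rest_pressure_cmH2O)
  gt <- simulate_boundary(tube, rest, geom, catheter_offset_mm = c(1, 0))
  expect_equal(max(gt$boundary_mm[1, ]), 9, tolerance = 1e-6)
  expect_equal(min(gt$boundary_mm[1, ]), 7, tolerance = 1e-6)
  # polygon area of the boundary equals the true CSA (conservation)
  expect_equal(boundary_to_csa(gt$boundary_mm[1, ]), gt$csa_mm2[1],
               tolerance = 1e-3)
  expect_error(
    simulate_boundary(tube, rest, geom, catheter_offset_mm = c(8.2, 0)),
    "unusable")
})

test_that("renderer places surfaces, folds, and rejects the unrenderable", {
  geom <- small_geom(n_frames = 1)
  mmpp <- mm_per_px(geom)
  rest <- data.frame(time_s = seq(0, 0.05, by = 1 / 5000),
                     pressure_cmH2O = 5)
  # direct surface at 10 mm
  gt <- simulate_boundary(tube_model(10, 12.5, 2000, 0.45), rest, geom)
  st <- render_frames(gt, geom, speckle = FALSE)
  col <- st[, 1, 1]
  first_bright <- which(col > -95)[1]
  expect_equal(first_bright, ceiling(10 / mmpp + 0.5), tolerance = 1)
  # fold: surface at 14 mm renders at 2 * 12.5 - 14 = 11 mm
  gt2 <- simulate_boundary(tube_model(14, 17.5, 8000, 0.45), rest, geom)
  st2 <- render_frames(gt2, geom, speckle = FALSE)
  col2 <- st2[, 1, 1]
  deepest_bright <- max(which(col2 > -95))
  expect_equal(deepest_bright * mmpp, 2 * 12.5 - 14, tolerance = 2 * mmpp)
  # fold would land inside the sheath -> rejected
  gt3 <- simulate_boundary(tube_model(24.8, 31, 8000, 0.45), rest, geom)
  expect_error(render_frames(gt3, geom, speckle = FALSE), "sheath")
  # determinism under a fixed seed
  s1 <- render_frames(gt, geom, speckle = TRUE, seed = 4)
  s2 <- render_frames(gt, geom, speckle = TRUE, seed = 4)
  expect_identical(s1, s2)
})

test_that("A-line averaging equals the brute-force group mean", {
  m <- matrix(rep(1:5, each = 8), nrow = 5, byrow = TRUE)  # 5 x 8
  expect_equal(average_alines(m, 4), matrix(rep(1:5, each = 2), 5,
                                            byrow = TRUE))
  expect_equal(average_alines(matrix(c(0, 0, 0, 4), 1), 4),
               matrix(1, 1, 1))
  set.seed(2)
  r <- matrix(rnorm(12 * 24), 12, 24)
  got <- average_alines(r, 4)
  want <- sapply(seq_len(6), function(gp)
    rowMeans(r[, (4 * gp - 3):(4 * gp)]))
  expect_equal(got, want)
  expect_error(average_alines(matrix(0, 3, 10), 4), "divisible")
  # 3-D stacks are averaged frame by frame
  arr <- array(rnorm(12 * 24 * 2), dim = c(12, 24, 2))
  got3 <- average_alines(arr, 4)
  expect_equal(dim(got3), c(12, 6, 2))
  expect_equal(got3[, , 2], average_alines(arr[, , 2], 4))
})
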