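# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; geometries are scaled down from the
# full 1152 x 1248 x 500 acquisition so the suite stays fast, and tests that
# depend on absolute pixel sizes say so explicitly.

# small but realistic scan geometry (same 12.5 mm range and 40 Hz clock)
small_geom <- function(n_frames = 3, depth_px = 288, n_angles = 208) {
  scan_geometry(n_frames = n_frames, depth_px = depth_px,
                n_angles = n_angles, frame_rate = 40)
}

quiet_vent <- function(...) ventilator_params(noise_sd_cmH2O = 0, ...)

# a mid-sized airway-like tube: a = 8 mm, 2 mm wall, nCsC ~ 0.43 %/cmH2O
test_tube <- function(E = 2000) tube_model(8, 10, E, 0.45)

# Independent oracle for the thick-walled cylinder compliance: solve the
# plane-strain axisymmetric displacement ODE u'' + u'/r - u/r^2 = 0 with
# traction boundary conditions sigma_rr(a) = -p, sigma_rr(b) = 0 by central
# finite differences (tridiagonal system, Thomas algorithm), and return
# 100 * (dCSA/CSA) / dp.
lame_fd_ncsc <- function(a, b, E, nu, n = 1500, p = 1e-3) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  r <- seq(a, b, length.out = n)
  h <- r[2] - r[1]
  # interior: u_{i-1}(1/h^2 - 1/(2 h r)) + u_i(-2/h^2 - 1/r^2) +
  #           u_{i+1}(1/h^2 + 1/(2 h r)) = 0
  lower <- numeric(n); diagv <- numeric(n); upper <- numeric(n)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    lower[i] <- 1 / h^2 - 1 / (2 * h * r[i])
    diagv[i] <- -2 / h^2 - 1 / r[i]^2
    upper[i] <- 1 / h^2 + 1 / (2 * h * r[i])
  }
  # boundaries: sigma_rr = (lam + 2 mu) u' + lam u / r, one-sided 2nd order
  # at r = a: u' ~ (-3 u1 + 4 u2 - u3)/(2h); fold u3 via the ODE? simpler:
  # use ghost-free 2nd-order one-sided difference with 3 points, absorb the
  # third point by extending the tridiagonal system with elimination.
  # Here: first-order one-sided with fine mesh is adequate at n ~ 1500 for a
  # 1% tolerance, but use 2nd-order via elimination for safety.
  # at a: (lam+2mu)(-3u1+4u2-u3)/(2h) + lam u1/a = -p
  # eliminate u3 using the interior equation at i = 2.
  c2l <- 1 / h^2 - 1 / (2 * h * r[2])
  c2d <- -2 / h^2 - 1 / r[2]^2
  c2u <- 1 / h^2 + 1 / (2 * h * r[2])
  # u3 = -(c2l u1 + c2d u2)/c2u
  k <- lam + 2 * mu
  diagv[1] <- -3 * k / (2 * h) + lam / a + (k / (2 * h)) * (c2l / c2u)
  upper[1] <- 4 * k / (2 * h) + (k / (2 * h)) * (c2d / c2u)
  rhs[1] <- -p
  # at b: (lam+2mu)(3un - 4un1 + un2)/(2h) + lam un/b = 0, eliminate un2
  cml <- 1 / h^2 - 1 / (2 * h * r[n - 1])
  cmd <- -2 / h^2 - 1 / r[n - 1]^2
  cmu <- 1 / h^2 + 1 / (2 * h * r[n - 1])
  # un2 = -(cmd un1 + cmu un)/cml
  diagv[n] <- 3 * k / (2 * h) + lam / b - (k / (2 * h)) * (cmu / cml)
  lower[n] <- -4 * k / (2 * h) - (k / (2 * h)) * (cmd / cml)
  rhs[n] <- 0
  # Thomas algorithm
  cp <- numeric(n); dp_ <- numeric(n)
  cp[1] <- upper[1] / diagv[1]
  dp_[1] <- rhs[1] / diagv[1]
  for (i in 2:n) {
    m <- diagv[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp_[i] <- (rhs[i] - lower[i] * dp_[i - 1]) / m
  }
  u <- numeric(n)
  u[n] <- dp_[n]
  for (i in (n - 1):1) u[i] <- dp_[i] - cp[i] * u[i + 1]
  ua <- u[1]
  100 * 2 * ua / (a * p)
}

# render + segment one noiseless frame and return per-column radius error
# in pixels against the ground truth
roundtrip_errors <- function(gt, geom, frame = 1, speckle = FALSE,
                             seed = NULL, ...) {
  st <- render_frames(gt, geom, speckle = speckle, seed = seed)
  sp <- detect_sheath(st[, , frame], geom)
  seg <- segment_lumen(st[, , frame], geom, sheath_px = sp, ...)
  corr <- correct_aliasing(seg$surface_px, seg$aliased, geom)
  corr - gt$boundary_mm[frame, ] / mm_per_px(geom)
}

# simulate + render + segment + compliance for one tube; returns list with
# recovered and analytic nCsC
recover_ncsc <- function(tube, geom, speckle, noise_sd, seed,
                         offset = c(0.3, 0.2)) {
  vent <- ventilator_params(noise_sd_cmH2O = noise_sd)
  pr <- make_pressure(vent, geom, seed = seed)
  gt <- simulate_boundary(tube, pr, geom, catheter_offset_mm = offset)
  st <- render_frames(gt, geom, speckle = speckle, seed = seed + 1L)
  series <- segment_stack(st, geom)
  res <- scan_compliance(series, pr, frame_rate = geom$frame_rate)
  list(ncsc = res$ncsc_pct_per_cmH2O, truth = gt$ncsc_true, result = res,
       gt = gt)
}

# study design grid used by the statistics calibration tests: the shape of
# the animal study (3 intensities x 4 time points x 4 positions)
study_design <- function() {
  expand.grid(intensity = 1:3, time = c(-1, 0, 2, 4),
              position = c(0, 1 / 3, 2 / 3, 1))
}
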