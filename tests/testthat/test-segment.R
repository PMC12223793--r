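rest_trace <- function(p = 5, dur = 0.1)
  data.frame(time_s = seq(0, dur, by = 1 / 5000), pressure_cmH2O = p)

test_that("sheath detection matches the renderer placement to sub-pixel", {
  geom <- small_geom(n_frames = 1)
  gt <- simulate_boundary(test_tube(), rest_trace(), geom)
  st <- render_frames(gt, geom, speckle = FALSE)
  sp <- detect_sheath(st[, , 1], geom)
  expect_equal(sp, (0.85 / 2) / mm_per_px(geom), tolerance = 0.02)
  # reference-arm mismatch scales the detected sheath proportionally
  st2 <- render_frames(gt, geom, speckle = FALSE, apparent_scale = 1.1)
  expect_equal(detect_sheath(st2[, , 1], geom) / sp, 1.1, tolerance = 0.01)
  # pure noise floor: nothing to detect
  noise <- matrix(10 * log10(1e-11 * rexp(geom$depth_px * geom$n_angles)),
                  geom$depth_px, geom$n_angles)
  expect_error(detect_sheath(noise, geom), class = "aoctel_rejected")
})

test_that("scale calibration is the sheath-radius definition", {
  geom <- scan_geometry()
  expect_equal(calibrate_scale(39, geom), 0.425 / 39)
  # detected at nominal placement -> nominal scale
  expect_equal(calibrate_scale(0.425 / mm_per_px(geom), geom), mm_per_px(geom))
  expect_error(calibrate_scale(-3, geom))
})

test_that("calibration removes reference-arm scale differences (< 2%)", {
  geom <- small_geom(n_frames = 1)
  gt <- simulate_boundary(test_tube(), rest_trace(), geom)
  csas <- sapply(c(1, 0.93, 1.1), function(k) {
    st <- render_frames(gt, geom, speckle = FALSE, apparent_scale = k)
    sp <- detect_sheath(st[, , 1], geom)
    seg <- segment_lumen(st[, , 1], geom, sheath_px = sp)
    boundary_to_csa(seg$surface_px * calibrate_scale(sp, geom))
  })
  expect_lt(max(abs(csas / csas[1] - 1)), 0.02)
  expect_lt(abs(csas[1] / gt$csa_mm2[1] - 1), 0.005)
})

test_that("noiseless segmentation recovers a circular lumen within 1 px", {
  geom <- small_geom(n_frames = 1)
  gt <- simulate_boundary(tube_model(10, 12.5, 2000, 0.45), rest_trace(),
                          geom)
  err <- roundtrip_errors(gt, geom)
  expect_lt(max(abs(err)), 1)
})

test_that("speckled segmentation stays within 3 px median error", {
  geom <- small_geom(n_frames = 1)
  gt <- simulate_boundary(test_tube(), rest_trace(), geom,
                          catheter_offset_mm = c(0.8, -0.4))
  for (seed in 1:3) {
    err <- roundtrip_errors(gt, geom, speckle = TRUE, seed = seed)
    expect_lt(median(abs(err)), 3)
  }
})

test_that("seed depths veto implausible surfaces", {
  geom <- small_geom(n_frames = 1)
  gt <- simulate_boundary(test_tube(), rest_trace(), geom)
  st <- render_frames(gt, geom, speckle = FALSE)
  truth <- gt$boundary_mm[1, ] / mm_per_px(geom)
  seg <- segment_lumen(st[, , 1], geom, seed_depths = truth)
  expect_lt(max(abs(seg$surface_px - truth)), 1)
  # seeds far from any real surface leave columns undetected -> unusable
  expect_error(
    segment_lumen(st[, , 1], geom,
                  seed_depths = rep(60, geom$n_angles), seed_tol_px = 10),
    class = "aoctel_rejected")
})

test_that("tissue in contact with the sheath rejects the scan", {
  geom <- small_geom(n_frames = 1)
  # lumen barely wider than the sheath: surface inside the contact margin
  gt <- simulate_boundary(tube_model(0.5, 2.5, 2000, 0.45), rest_trace(),
                          geom)
  st <- render_frames(gt, geom, speckle = FALSE)
  expect_error(segment_lumen(st[, , 1], geom), class = "aoctel_rejected")
})

test_that("aliasing correction mirrors flagged runs and is an involution", {
  geom <- scan_geometry()               # full depth: 1152 px
  n <- 64
  surface <- rep(900, n)
  flags <- rep(FALSE, n)
  expect_identical(correct_aliasing(surface, flags, geom), surface)
  # 11 mm apparent in a flagged run -> 14 mm corrected (px: 2*1152 - r)
  mmpp <- mm_per_px(geom)
  surface[20:40] <- c(1150, rep(11 / mmpp, 19), 1150)
  flags[20:40] <- TRUE
  corr <- correct_aliasing(surface, flags, geom)
  expect_equal(corr[25] * mmpp, 2 * 12.5 - 11)
  expect_identical(correct_aliasing(corr, flags, geom), surface)
  expect_identical(corr[!flags], surface[!flags])
  # a flagged run away from the bottom is inconsistent
  bad_flags <- rep(FALSE, n); bad_flags[5:8] <- TRUE
  expect_error(correct_aliasing(rep(500, n), bad_flags, geom),
               "inconsistent fold region")
})

test_that("fold round-trip recovers radii beyond the range within 1 px", {
  geom <- scan_geometry(n_frames = 2, depth_px = 768, n_angles = 624)
  tube <- tube_model(13, 16, 8000, 0.45)
  gt <- simulate_boundary(tube, rest_trace(), geom,
                          catheter_offset_mm = c(1, 0))
  expect_gt(max(gt$boundary_mm), 12.5)  # genuinely beyond the range
  err <- roundtrip_errors(gt, geom)
  expect_lt(max(abs(err)), 1)
  # the segmenter flags the aliased sector it was rendered with
  st <- render_frames(gt, geom, speckle = FALSE)
  seg <- segment_lumen(st[, , 1], geom)
  truly_aliased <- gt$boundary_mm[1, ] > 12.5
  expect_gt(mean(seg$aliased == truly_aliased), 0.95)
})

test_that("polygon CSA matches closed forms and is translation invariant", {
  n <- 1248
  expect_equal(boundary_to_csa(rep(10, n)), pi * 100, tolerance = 1e-3)
  # catheter 1 mm off-axis: same circle, same area
  th <- 2 * pi * (seq_len(n) - 1) / n
  off <- cos(th) + sqrt(100 - sin(th)^2)
  expect_equal(boundary_to_csa(off), pi * 100, tolerance = 1e-3)
  # ellipse 10 x 8 mm: pi * a * b = 251.327
  ell <- 10 * 8 / sqrt((8 * cos(th))^2 + (10 * sin(th))^2)
  expect_equal(boundary_to_csa(ell), pi * 80, tolerance = pi * 80 * 1e-3)
  # NA columns are interpolated circularly
  gap <- rep(10, n); gap[5:40] <- NA
  expect_equal(boundary_to_csa(gap), pi * 100, tolerance = 1e-3)
  expect_error(boundary_to_csa(c(10, NA, NA, 10)), "3 valid")
})

test_that("segment_stack produces a calibrated, consistent CSA series", {
  geom <- small_geom(n_frames = 4)
  gt <- simulate_boundary(test_tube(), rest_trace(p = 12), geom,
                          catheter_offset_mm = c(0.5, 0.2))
  st <- render_frames(gt, geom, speckle = FALSE)
  series <- segment_stack(st, geom)
  expect_s3_class(series, "csa_series")
  expect_equal(nrow(series$csa), 4)
  expect_true(all(diff(series$csa$time_s) > 0))
  expect_lt(max(abs(series$csa$csa_mm2 / gt$csa_mm2 - 1)), 0.005)
})
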