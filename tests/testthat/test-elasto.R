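test_that("frame pressure statistics use half-open frame windows", {
  geom <- scan_geometry(n_frames = 20)
  times <- frame_times(geom)
  const <- data.frame(time_s = seq(0, 0.5 - 1e-9, by = 1 / 5000),
                      pressure_cmH2O = 10)
  fp <- frame_pressure_stats(const, times, 40)
  expect_equal(fp$mean_cmH2O, rep(10, 20))
  expect_equal(fp$sd_cmH2O, rep(0, 20))
  # 5 kHz / 40 Hz = 125 samples per window
  tr <- make_pressure(quiet_vent(), geom)
  fp2 <- frame_pressure_stats(tr, times, 40)
  expect_equal(unique(fp2$n_samples), 125)
  # linear ramp over one frame: mean 1/2 up to one-sample quantization
  ramp <- data.frame(time_s = seq(0, 1 / 40, length.out = 126)[1:125])
  ramp$pressure_cmH2O <- ramp$time_s * 40
  fp3 <- frame_pressure_stats(ramp, 0, 40)
  expect_equal(fp3$mean_cmH2O, 0.5, tolerance = 0.01)
  # a frame window with no samples is rejected
  expect_error(frame_pressure_stats(const, c(0, 10), 40), "no pressure")
})

test_that("cycle detection finds the breaths and rejects flat signals", {
  geom <- scan_geometry()
  fp <- frame_pressure_stats(make_pressure(quiet_vent(), geom),
                             frame_times(geom), 40)
  cyc <- detect_cycles(fp$mean_cmH2O, 40, 20)
  expect_equal(nrow(cyc), 4)            # 12.5 s at 3 s per breath
  expect_true(all(cyc$end > cyc$start))
  expect_error(detect_cycles(rep(7, 500), 40, 20),
               class = "aoctel_rejected")
  expect_error(detect_cycles(fp$mean_cmH2O[1:100], 40, 20),
               class = "aoctel_rejected")
})

test_that("cycle detection tolerates sensor noise and cardiac ripple", {
  geom <- scan_geometry()
  fp <- frame_pressure_stats(make_pressure(ventilator_params(), geom,
                                           seed = 8),
                             frame_times(geom), 40)
  expect_equal(nrow(detect_cycles(fp$mean_cmH2O, 40, 20)), 4)
  # CSA channel with 1.5 Hz ripple still yields the 4 breath cycles
  t <- frame_times(geom)
  csa <- 200 + 12 * ventilator_waveform(t, quiet_vent()) / 18 +
    2 * sin(2 * pi * 1.5 * t)
  expect_equal(nrow(detect_cycles(csa, 40, 20)), 4)
})

test_that("per-cycle extrema are lag-robust and drop runt cycles", {
  geom <- scan_geometry()
  vent <- quiet_vent()
  t <- frame_times(geom)
  p <- ventilator_waveform(t, vent)
  csa <- 190 + (p - 5)                  # perfectly coupled
  cyc <- detect_cycles(p, 40, 20)
  ext <- cycle_extrema(csa, p, cyc)
  expect_equal(ext$max_p, rep(18, nrow(ext)))
  expect_equal(ext$min_p, rep(5, nrow(ext)))
  expect_equal(ext$max_csa, rep(203, nrow(ext)))
  # a 100 ms lag between channels leaves per-cycle extrema unchanged
  lagged <- 190 + (ventilator_waveform(t - 0.1, vent) - 5)
  ext_lag <- cycle_extrema(lagged, p, cyc)
  expect_equal(ext_lag$max_csa, ext$max_csa, tolerance = 1e-6)
  expect_equal(ext_lag$min_csa, ext$min_csa, tolerance = 1e-6)
  # monotone CSA within a cycle: extrema at the cycle ends
  mono <- seq_along(t)
  extm <- cycle_extrema(mono, p, cyc)
  expect_equal(extm$frame_max, cyc$end - 1)
  expect_equal(extm$frame_min, cyc$start)
  # cycles shorter than 4 frames are dropped; < 2 left is an error
  tiny <- data.frame(start = c(1, 3, 5), end = c(3, 5, 7))
  expect_error(cycle_extrema(csa[1:10], p[1:10], tiny),
               class = "aoctel_rejected")
})

test_that("compliance implements the defining arithmetic", {
  ext <- data.frame(cycle = 1:2, max_csa = 205, min_csa = 195,
                    max_p = 15.5, min_p = 10.5,
                    frame_max = c(30, 150), frame_min = c(90, 210))
  res <- compliance(ext, csa = rep(200, 300))
  expect_equal(res$d_csa_mm2, 10)
  expect_equal(res$d_p_cmH2O, 5)
  expect_equal(res$csa_bar_mm2, 200)
  expect_equal(res$cc_mm2_per_cmH2O, 2)
  expect_equal(res$ncsc_pct_per_cmH2O, 1)   # 100 * (10/200)/5
  expect_equal(res$n_cycles, 2)
})

test_that("nCsC is invariant under uniform CSA rescaling, CC is not", {
  geom <- scan_geometry()
  vent <- quiet_vent()
  t <- frame_times(geom)
  p <- ventilator_waveform(t, vent)
  csa <- 150 + 10 * (p - 5) / 13
  cyc <- detect_cycles(p, 40, 20)
  r1 <- compliance(cycle_extrema(csa, p, cyc), csa)
  r4 <- compliance(cycle_extrema(4 * csa, p, cyc), 4 * csa)
  expect_equal(r4$cc_mm2_per_cmH2O, 4 * r1$cc_mm2_per_cmH2O)
  expect_equal(r4$ncsc_pct_per_cmH2O, r1$ncsc_pct_per_cmH2O)
})

test_that("CSA uncertainty windows follow the +/-5-frame rule", {
  set.seed(11)
  csa <- 200 + rnorm(300, sd = 2)
  ext <- data.frame(cycle = 1:2, max_csa = c(210, 211), min_csa = c(191, 190),
                    max_p = 18, min_p = 5,
                    frame_max = c(40, 160), frame_min = c(100, 220))
  res <- compliance(ext, csa)
  by_hand <- function(f) sd(csa[(f - 5):(f + 5)])
  expect_equal(res$sd_max_csa, mean(c(by_hand(40), by_hand(160))))
  expect_equal(res$sd_min_csa, mean(c(by_hand(100), by_hand(220))))
  expect_equal(res$sd_csa_bar,
               sqrt(res$sd_max_csa^2 + res$sd_min_csa^2))
  expect_gte(res$sd_csa_bar, max(res$sd_max_csa, res$sd_min_csa))
  res2 <- compliance(ext, csa, sd_rule = "sum_of_roots")
  expect_equal(res2$sd_csa_bar, res2$sd_max_csa + res2$sd_min_csa)
  # extremum too close to the scan edge truncates with a warning
  ext_edge <- ext; ext_edge$frame_max <- c(3, 160)
  expect_warning(compliance(ext_edge, csa), "truncated")
  # no pressure modulation
  ext_flat <- ext; ext_flat$max_p <- 5
  expect_error(compliance(ext_flat, csa), class = "aoctel_rejected")
})

test_that("lag between pressure and CSA barely moves nCsC", {
  geom <- scan_geometry()
  vent <- quiet_vent()
  t <- frame_times(geom)
  p <- ventilator_waveform(t, vent)
  cyc <- detect_cycles(p, 40, 20)
  base <- NULL
  for (lag in c(0, 0.25, -0.25) * 3) {  # up to a quarter cycle
    csa <- 200 + 15 * (ventilator_waveform(t - lag, vent) - 5) / 13
    # lagged extrema can sit at the scan edge; the truncation warning is the
    # documented behaviour and not under test here
    r <- suppressWarnings(compliance(cycle_extrema(csa, p, cyc), csa))
    if (is.null(base)) base <- r$ncsc_pct_per_cmH2O
    expect_equal(r$ncsc_pct_per_cmH2O, base, tolerance = 0.03)
  }
})

test_that("noiseless end-to-end compliance matches the analytic value", {
  geom <- small_geom(n_frames = 280)
  out <- recover_ncsc(test_tube(), geom, speckle = FALSE, noise_sd = 0,
                      seed = 1)
  expect_equal(out$ncsc, out$truth, tolerance = 0.05)
  expect_gte(out$result$n_cycles, 2)
})

test_that("doubling the pressure modulation doubles dCSA, not nCsC", {
  geom <- small_geom(n_frames = 280)
  tube <- tube_model(8, 10, 4000, 0.45)  # stiff: small-strain regime
  runs <- lapply(c(1, 0.5), function(att) {
    pr <- make_pressure(quiet_vent(attenuation = att), geom)
    gt <- simulate_boundary(tube, pr, geom)
    fp <- frame_pressure_stats(pr, frame_times(geom), 40)
    cyc <- detect_cycles(fp$mean_cmH2O, 40, 20)
    compliance(cycle_extrema(gt$csa_mm2, fp$mean_cmH2O, cyc), gt$csa_mm2)
  })
  expect_equal(runs[[1]]$d_csa_mm2, 2 * runs[[2]]$d_csa_mm2,
               tolerance = 0.02)
  expect_equal(runs[[1]]$ncsc_pct_per_cmH2O, runs[[2]]$ncsc_pct_per_cmH2O,
               tolerance = 0.02)
})
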