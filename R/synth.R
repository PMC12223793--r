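#' Generate a pressure-controlled ventilator pressure trace
#'
#' Produces the high-rate intraluminal pressure recording for one scan:
#' a periodic smoothed-trapezoid waveform (cosine rise to a plateau near
#' `peep + attenuation * (mip - peep)`, cosine fall back to PEEP) sampled at
#' `geom$pressure_rate`, plus additive white sensor noise.
#'
#' The scan duration is `geom$n_frames / geom$frame_rate` seconds; with the
#' default 500 frames at 40 Hz this is 12.5 s, covering four complete breaths
#' at 20 breaths/min.
#'
#' @param vent A [ventilator_params()].
#' @param geom A [scan_geometry()].
#' @param seed Integer seed for the sensor noise (`NULL` leaves the RNG
#'   state alone).
#' @return A data frame with columns `time_s` and `pressure_cmH2O`.
#' @examples
#' tr <- make_pressure(ventilator_params(), scan_geometry(n_frames = 100))
#' range(tr$time_s)
#' @export
make_pressure <- function(vent = ventilator_params(), geom = scan_geometry(),
                          seed = NULL) {
  stopifnot(inherits(vent, "ventilator_params"),
            inherits(geom, "scan_geometry"))
  duration <- geom$n_frames / geom$frame_rate
  if (!is.finite(duration) || duration <= 0)
    stop("make_pressure: scan duration must be positive")
  n <- round(duration * geom$pressure_rate)
  t <- (seq_len(n) - 1) / geom$pressure_rate
  p <- ventilator_waveform(t, vent)
  if (vent$noise_sd_cmH2O > 0) {
    if (!is.null(seed)) set.seed(seed)
    p <- p + stats::rnorm(n, sd = vent$noise_sd_cmH2O)
  }
  data.frame(time_s = t, pressure_cmH2O = p)
}

#' Noiseless ventilator waveform evaluated at arbitrary times
#'
#' The deterministic part of the pressure trace: period `60/breaths_per_min`
#' seconds, baseline at PEEP, plateau at
#' `peep + attenuation * (mip - peep)`. Within each period the phase is split
#' into a cosine rise (first 30% of the inspiratory fraction), a plateau
#' (remainder of inspiration), a cosine fall (30% of expiration), and the
#' PEEP baseline.
#'
#' @param t Times in seconds.
#' @param vent A [ventilator_params()].
#' @return Pressures in cmH2O, same length as `t`.
#' @export
ventilator_waveform <- function(t, vent) {
  period <- 60 / vent$breaths_per_min
  u <- (t / period) %% 1
  f <- vent$insp_fraction
  rise_end <- 0.3 * f
  fall_end <- f + 0.3 * (1 - f)
  w <- numeric(length(u))
  i <- u < rise_end
  w[i] <- (1 - cos(pi * u[i] / rise_end)) / 2
  i <- u >= rise_end & u < f
  w[i] <- 1
  i <- u >= f & u < fall_end
  w[i] <- (1 + cos(pi * (u[i] - f) / (fall_end - f))) / 2
  vent$peep_cmH2O + vent$attenuation * (vent$mip_cmH2O - vent$peep_cmH2O) * w
}

#' Analytic normalized cross-sectional compliance of a thick-walled tube
#'
#' Closed-form nCsC of a pressurized thick-walled cylinder in plane strain
#' (the Lame solution). For inner radius `a`, outer radius `b`, Young's
#' modulus `E` and Poisson ratio `nu`, a small internal pressure increment
#' `dp` displaces the inner wall by
#' `u(a) = dp * a * (1 + nu) * ((1 - 2 nu) a^2 + b^2) / (E (b^2 - a^2))`,
#' so the fractional area change per unit pressure is `2 u(a) / (a dp)` and
#'
#' `nCsC = 100 * 2 (1 + nu) ((1 - 2 nu) a^2 + b^2) / (E (b^2 - a^2))`
#'
#' in percent per cmH2O when `E` is in cmH2O. The value depends only on the
#' ratio `b/a`, not on absolute size, and is inversely proportional to `E`.
#'
#' @param tube A [tube_model()].
#' @return nCsC in %/cmH2O.
#' @examples
#' analytic_ncsc(tube_model(8, 10, 2000, 0.45))
#' @export
analytic_ncsc <- function(tube) {
  stopifnot(inherits(tube, "tube_model"))
  a <- tube$inner_radius_mm
  b <- tube$outer_radius_mm
  E <- tube$youngs_modulus_cmH2O
  nu <- tube$poisson
  if (b <= a) stop("analytic_ncsc: requires b > a")
  100 * 2 * (1 + nu) * ((1 - 2 * nu) * a^2 + b^2) / (E * (b^2 - a^2))
}

#' Simulate the ground-truth lumen boundary of a ventilated elastic tube
#'
#' Drives a [tube_model()] quasi-statically with a pressure trace: the lumen
#' cross-sectional area responds linearly to the frame-averaged transmural
#' pressure,
#' `CSA(p) = pi a^2 (1 + (nCsC/100) (p - p0))`,
#' with `nCsC` from [analytic_ncsc()] (the radius therefore scales as the
#' square root of that factor). An optional sinusoidal cardiac modulation
#' multiplies the CSA, and the boundary is re-expressed as radii from a
#' catheter axis displaced by `catheter_offset_mm` from the tube axis.
#'
#' @param tube A [tube_model()].
#' @param pressure Data frame `time_s, pressure_cmH2O` (see
#'   [make_pressure()]). The wall responds to the frame-window mean of this
#'   trace.
#' @param geom A [scan_geometry()].
#' @param catheter_offset_mm Length-2 numeric, catheter axis position
#'   relative to the tube axis, mm.
#' @param cardiac_amp Fractional CSA modulation amplitude (0 disables).
#' @param cardiac_hz Cardiac modulation frequency, Hz.
#' @return An object of class `aoct_ground_truth`: list with `boundary_mm`
#'   (`n_frames x n_angles` matrix of radii from the catheter axis),
#'   `csa_mm2`, `frame_time_s`, `pressure` (the input trace), `ncsc_true`,
#'   `catheter_offset_mm`, `tube`, `geom`.
#' @export
simulate_boundary <- function(tube, pressure, geom = scan_geometry(),
                              catheter_offset_mm = c(0, 0),
                              cardiac_amp = 0, cardiac_hz = 1.5) {
  stopifnot(inherits(tube, "tube_model"), inherits(geom, "scan_geometry"),
            is.data.frame(pressure),
            all(c("time_s", "pressure_cmH2O") %in% names(pressure)),
            length(catheter_offset_mm) == 2)
  ncsc <- analytic_ncsc(tube)
  fp <- frame_pressure_stats(pressure, frame_times(geom), geom$frame_rate)
  s <- ncsc / 100
  area_factor <- 1 + s * (fp$mean_cmH2O - tube$rest_pressure_cmH2O)
  if (any(area_factor <= 0))
    stop("simulate_boundary: pressure excursion collapses the lumen; ",
         "reduce modulation or stiffen the tube")
  t_mid <- frame_times(geom) + 0.5 / geom$frame_rate
  if (cardiac_amp > 0)
    area_factor <- area_factor *
      (1 + cardiac_amp * sin(2 * pi * cardiac_hz * t_mid))
  a <- tube$inner_radius_mm
  radius_t <- a * sqrt(area_factor)          # circle radius about tube axis
  d <- sqrt(sum(catheter_offset_mm^2))
  if (d >= min(radius_t))
    stop("simulate_boundary: catheter offset (", signif(d, 3),
         " mm) reaches the wall (min radius ", signif(min(radius_t), 3),
         " mm); scan would be unusable")
  theta <- 2 * pi * (seq_len(geom$n_angles) - 1) / geom$n_angles
  # tube centre seen from the catheter axis
  phi <- atan2(-catheter_offset_mm[2], -catheter_offset_mm[1])
  dth <- theta - phi
  # star-shaped boundary of an offset circle: r(theta) from the catheter axis
  boundary <- outer(radius_t, dth, function(R, ang)
    d * cos(ang) + sqrt(R^2 - (d * sin(ang))^2))
  gt <- list(boundary_mm = boundary,
             csa_mm2 = pi * radius_t^2,
             frame_time_s = frame_times(geom),
             pressure = pressure,
             ncsc_true = ncsc,
             catheter_offset_mm = catheter_offset_mm,
             tube = tube, geom = geom)
  class(gt) <- "aoct_ground_truth"
  gt
}

#' @export
print.aoct_ground_truth <- function(x, ...) {
  cat(sprintf(
    "aOCT ground truth: %d frames x %d angles, CSA %.3g-%.3g mm2, true nCsC %.4g %%/cmH2O\n",
    nrow(x$boundary_mm), ncol(x$boundary_mm), min(x$csa_mm2), max(x$csa_mm2),
    x$ncsc_true))
  invisible(x)
}

#' Frame start times of a scan
#'
#' @param geom A [scan_geometry()].
#' @return Numeric vector of rotation start times, seconds.
#' @export
frame_times <- function(geom) (seq_len(geom$n_frames) - 1) / geom$frame_rate

# one-way sensitivity in dB at physical depth z (mm), log-linear between the
# stated endpoints (105 dB at 1 mm, 55 dB at 8.5 mm), extrapolated beyond
sensitivity_db <- function(z) 105 - (105 - 55) / (8.5 - 1) * (z - 1)

# relative amplitude roll-off (1 at 1 mm)
rolloff_amp <- function(z) 10^((sensitivity_db(z) - 105) / 20)

#' Render polar aOCT frames from a ground-truth boundary
#'
#' Produces a stack of log-compressed (dB-scale) polar intensity frames with:
#' a bright sheath ring around the catheter axis; a scattering tissue band
#' starting at the boundary radius whose intensity decays exponentially with
#' depth into the tissue (`attenuation_db_mm`, round-trip intensity dB per
#' mm, giving an effectively ~1-2 mm visible wall); a depth-dependent
#' system sensitivity roll-off interpolating 105 dB at 1 mm to 55 dB at
#' 8.5 mm (log-linear in dB, extrapolated beyond); fully developed
#' multiplicative speckle (exponential intensity statistics) on reflectors;
#' an additive exponential noise floor; and fold-over aliasing: any
#' reflector whose apparent radius exceeds the imaging range is mirrored to
#' `2*range - r`, so a folded wall appears upside down with its surface as
#' the deepest, brightest edge of the mirrored haze.
#'
#' `apparent_scale` emulates a reference-arm length mismatch by scaling all
#' apparent radii (sheath included); downstream sheath-based calibration must
#' undo it.
#'
#' @param gt An `aoct_ground_truth` from [simulate_boundary()].
#' @param geom A [scan_geometry()]; defaults to the one inside `gt`.
#' @param speckle Logical; render speckle and noise (TRUE) or the
#'   deterministic mean image (FALSE).
#' @param noise_floor_db Intensity of the noise floor in dB relative to a
#'   perfect reflector at 1 mm.
#' @param attenuation_db_mm Round-trip intensity attenuation in tissue,
#'   dB/mm.
#' @param sheath_thickness_mm Radial thickness of the sheath ring.
#' @param apparent_scale Reference-arm mismatch factor (1 = matched).
#' @param seed Integer seed for speckle/noise.
#' @return A numeric array `depth_px x n_angles x n_frames` of dB intensities
#'   with attribute `time_s` (frame timestamps).
#' @export
render_frames <- function(gt, geom = gt$geom, speckle = TRUE,
                          noise_floor_db = -110, attenuation_db_mm = 20,
                          sheath_thickness_mm = 0.1, apparent_scale = 1,
                          seed = NULL) {
  stopifnot(inherits(gt, "aoct_ground_truth"), inherits(geom, "scan_geometry"))
  if (nrow(gt$boundary_mm) != geom$n_frames ||
      ncol(gt$boundary_mm) != geom$n_angles)
    stop("render_frames: ground truth and geometry disagree on frame/angle counts")
  k <- apparent_scale
  sheath_r <- geom$sheath_od_mm / 2 * k
  max_renderable <- (2 * geom$range_mm - sheath_r) / k
  if (any(gt$boundary_mm > max_renderable))
    stop("render_frames: boundary radius exceeds ", signif(max_renderable, 4),
         " mm; fold-over would land inside the sheath")
  if (!is.null(seed)) set.seed(seed)
  mmpp <- mm_per_px(geom)
  z1 <- (seq_len(geom$depth_px) - 0.5) * mmpp / k  # physical depth per row
  z2 <- 2 * geom$range_mm / k - z1                 # folded counterpart
  roll1 <- rolloff_amp(z1)
  roll2 <- rolloff_amp(z2)
  # sheath ring with partial-volume coverage at its edges, so its outer
  # radius is defined to sub-pixel precision (it is the calibration target)
  z_lo <- (seq_len(geom$depth_px) - 1) * mmpp
  z_hi <- seq_len(geom$depth_px) * mmpp
  cov <- pmax(0, pmin(z_hi, sheath_r) -
                   pmax(z_lo, sheath_r - sheath_thickness_mm * k)) /
    (mmpp)
  sheath_int <- rolloff_amp(z1)^2 * cov
  nf <- 10^(noise_floor_db / 10)
  att <- attenuation_db_mm
  wall_amp <- function(z, roll, r_app) {
    # amplitude of the attenuated wall at physical depth z for each column
    pen <- outer(z, r_app, "-")              # penetration depth into tissue
    inside <- pen >= 0
    (roll * inside) * 10^(-att * pmax(pen, 0) / 20)
  }
  out <- array(0, dim = c(geom$depth_px, geom$n_angles, geom$n_frames))
  for (f in seq_len(geom$n_frames)) {
    r_phys <- gt$boundary_mm[f, ]
    amp <- wall_amp(z1, roll1, r_phys) + wall_amp(z2, roll2, r_phys)
    inten <- amp^2 + sheath_int
    if (speckle) {
      np <- length(inten)
      inten <- inten * stats::rexp(np) + nf * stats::rexp(np)
    } else {
      inten <- inten + nf
    }
    out[, , f] <- 10 * log10(inten)
  }
  attr(out, "time_s") <- gt$frame_time_s
  out
}

#' Average raw A-lines in angular groups
#'
#' Collapses a raw frame (or stack) whose column count is
#' `n_angles * aline_group` into `n_angles` columns by arithmetic averaging
#' of each consecutive group, leaving depth untouched.
#'
#' @param x Matrix (`depth x raw_columns`) or 3-D array
#'   (`depth x raw_columns x frames`).
#' @param group Number of consecutive columns per group.
#' @return Same structure with `raw_columns / group` columns.
#' @export
average_alines <- function(x, group = 4) {
  stopifnot(group >= 1)
  avg1 <- function(m) {
    nc <- ncol(m)
    if (nc %% group != 0)
      stop("average_alines: column count ", nc,
           " is not divisible by group size ", group)
    idx <- rep(seq_len(nc / group), each = group)
    out <- t(rowsum(t(m), idx) / group)
    dimnames(out) <- NULL
    out
  }
  if (is.matrix(x)) return(avg1(x))
  if (length(dim(x)) == 3) {
    first <- avg1(x[, , 1])
    out <- array(0, dim = c(nrow(first), ncol(first), dim(x)[3]))
    out[, , 1] <- first
    if (dim(x)[3] > 1)
      for (f in 2:dim(x)[3]) out[, , f] <- avg1(x[, , f])
    attr(out, "time_s") <- attr(x, "time_s")
    return(out)
  }
  stop("average_alines: expected a matrix or a 3-D array")
}
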