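#' Acquisition geometry of a rotational aOCT scan
#'
#' Bundles the acquisition constants shared by the frame renderer and the
#' segmenter: rotation (frame) rate, number of frames, image depth in pixels
#' and millimetres, angular sampling, A-line averaging group, catheter sheath
#' outer diameter, and the pressure-channel sampling rate.
#'
#' Defaults correspond to a long-range endoscopic system rotating at 40 Hz,
#' producing ~500 frames of 1152 depth pixels (12.5 mm range) by 1248 angular
#' columns (after averaging raw A-lines in groups of 4), with a 0.85 mm OD
#' sheath and a 5 kHz intraluminal pressure channel.
#'
#' @param frame_rate Catheter rotation rate in rotations/s (one frame per
#'   rotation).
#' @param n_frames Number of frames in a scan.
#' @param depth_px Number of depth pixels per A-line.
#' @param range_mm Physical imaging range covered by `depth_px`, in mm.
#' @param n_angles Number of angular columns per frame (after A-line
#'   averaging).
#' @param aline_group Number of raw A-lines averaged into one column.
#' @param sheath_od_mm Outer diameter of the catheter sheath, mm.
#' @param pressure_rate Pressure sampling rate, samples/s.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()
#' g$n_frames / g$frame_rate  # scan duration, seconds
#' @export
scan_geometry <- function(frame_rate = 40, n_frames = 500, depth_px = 1152,
                          range_mm = 12.5, n_angles = 1248, aline_group = 4,
                          sheath_od_mm = 0.85, pressure_rate = 5000) {
  stopifnot(frame_rate > 0, range_mm > 0, pressure_rate > 0,
            depth_px >= 1, n_angles >= 1, n_frames >= 1,
            aline_group >= 1, sheath_od_mm > 0)
  g <- list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
            depth_px = as.integer(depth_px), range_mm = range_mm,
            n_angles = as.integer(n_angles),
            aline_group = as.integer(aline_group),
            sheath_od_mm = sheath_od_mm, pressure_rate = pressure_rate)
  class(g) <- "scan_geometry"
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "aOCT scan geometry: %d frames @ %g Hz (%.3g s), %d px over %g mm (%.4g um/px),\n  %d angular columns (A-lines averaged by %d), sheath OD %g mm, pressure @ %g Hz\n",
    x$n_frames, x$frame_rate, x$n_frames / x$frame_rate, x$depth_px,
    x$range_mm, 1000 * x$range_mm / x$depth_px, x$n_angles, x$aline_group,
    x$sheath_od_mm, x$pressure_rate))
  invisible(x)
}

#' Nominal axial pixel scale of a geometry
#'
#' @param geom A [scan_geometry()].
#' @return Millimetres per depth pixel.
#' @export
mm_per_px <- function(geom) geom$range_mm / geom$depth_px

#' Ground-truth mechanical model: thick-walled linearly elastic tube
#'
#' Describes the airway as a homogeneous, isotropic, linearly elastic
#' thick-walled cylinder with inner radius `a`, outer radius `b`, Young's
#' modulus `E` (in cmH2O so compliance comes out per cmH2O), and Poisson
#' ratio `nu`. `rest_pressure_cmH2O` is the transmural pressure at which the
#' tube sits at its reference radius `a`.
#'
#' @param inner_radius_mm Inner (lumen) radius at rest, mm.
#' @param outer_radius_mm Outer wall radius, mm.
#' @param youngs_modulus_cmH2O Young's modulus, cmH2O (1 cmH2O ~ 98.07 Pa).
#' @param poisson Poisson ratio in `[0, 0.5)`.
#' @param rest_pressure_cmH2O Reference transmural pressure, cmH2O.
#' @return An object of class `tube_model`.
#' @examples
#' tm <- tube_model(8, 10, 2000, 0.45)
#' analytic_ncsc(tm)
#' @export
tube_model <- function(inner_radius_mm = 8, outer_radius_mm = 10,
                       youngs_modulus_cmH2O = 2000, poisson = 0.45,
                       rest_pressure_cmH2O = 5) {
  stopifnot(inner_radius_mm > 0, youngs_modulus_cmH2O > 0,
            poisson >= 0, poisson < 0.5)
  if (outer_radius_mm <= inner_radius_mm)
    stop("tube_model: outer radius must exceed inner radius (b > a)")
  tm <- list(inner_radius_mm = inner_radius_mm,
             outer_radius_mm = outer_radius_mm,
             youngs_modulus_cmH2O = youngs_modulus_cmH2O,
             poisson = poisson,
             rest_pressure_cmH2O = rest_pressure_cmH2O)
  class(tm) <- "tube_model"
  tm
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf(
    "thick-walled elastic tube: a = %g mm, b = %g mm, E = %g cmH2O, nu = %g, p0 = %g cmH2O\n  analytic nCsC = %.4g %%/cmH2O\n",
    x$inner_radius_mm, x$outer_radius_mm, x$youngs_modulus_cmH2O, x$poisson,
    x$rest_pressure_cmH2O, analytic_ncsc(x)))
  invisible(x)
}

#' Pressure-controlled ventilator waveform parameters
#'
#' Parameters of the periodic intraluminal pressure waveform and of nuisance
#' terms layered on top of it. The waveform is a smoothed trapezoid: rise to
#' a plateau near `peep + attenuation * (mip - peep)`, fall back to the PEEP
#' baseline; `insp_fraction` is the fraction of the breath period spent in
#' inspiration (rise + plateau). `attenuation` models the position-dependent
#' reduction of the pressure modulation amplitude along the airway (1 at the
#' distal/carina end). `cardiac_amp` is a fractional cross-sectional-area
#' modulation at `cardiac_hz`, emulating cardiac coupling; it affects the
#' lumen, not the pressure channel. `noise_sd_cmH2O` is additive white sensor
#' noise on the sampled pressure (default matches a ~1.32 cmH2O sensitivity
#' probe).
#'
#' @param breaths_per_min Respiratory rate, breaths/min.
#' @param mip_cmH2O Maximum inspiratory pressure, cmH2O.
#' @param peep_cmH2O Positive end-expiratory pressure, cmH2O.
#' @param insp_fraction Inspiratory fraction of the period, in (0, 1).
#' @param attenuation Modulation-amplitude factor in (0, 1].
#' @param cardiac_amp Fractional CSA modulation amplitude (0 disables).
#' @param cardiac_hz Cardiac modulation frequency, Hz.
#' @param noise_sd_cmH2O Pressure sensor noise standard deviation, cmH2O.
#' @return An object of class `ventilator_params`.
#' @export
ventilator_params <- function(breaths_per_min = 20, mip_cmH2O = 18,
                              peep_cmH2O = 5, insp_fraction = 1 / 3,
                              attenuation = 1, cardiac_amp = 0,
                              cardiac_hz = 1.5, noise_sd_cmH2O = 1.32) {
  stopifnot(breaths_per_min > 0, peep_cmH2O >= 0,
            insp_fraction > 0, insp_fraction < 1,
            attenuation > 0, attenuation <= 1,
            cardiac_amp >= 0, cardiac_hz > 0, noise_sd_cmH2O >= 0)
  if (mip_cmH2O <= peep_cmH2O)
    stop("ventilator_params: MIP must exceed PEEP")
  v <- list(breaths_per_min = breaths_per_min, mip_cmH2O = mip_cmH2O,
            peep_cmH2O = peep_cmH2O, insp_fraction = insp_fraction,
            attenuation = attenuation, cardiac_amp = cardiac_amp,
            cardiac_hz = cardiac_hz, noise_sd_cmH2O = noise_sd_cmH2O)
  class(v) <- "ventilator_params"
  v
}

#' @export
print.ventilator_params <- function(x, ...) {
  cat(sprintf(
    "ventilator: %g breaths/min, MIP %g / PEEP %g cmH2O, insp fraction %.3g,\n  attenuation %g, cardiac amp %g @ %g Hz, sensor noise sd %g cmH2O\n",
    x$breaths_per_min, x$mip_cmH2O, x$peep_cmH2O, x$insp_fraction,
    x$attenuation, x$cardiac_amp, x$cardiac_hz, x$noise_sd_cmH2O))
  invisible(x)
}
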