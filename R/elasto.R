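#' Per-frame statistics of the high-rate pressure trace
#'
#' Synchronizes the pressure channel with the frame clock: for each frame the
#' mean and standard deviation of all pressure samples falling in the
#' half-open window `[t_frame, t_frame + 1/frame_rate)` are computed. With a
#' 5 kHz trace and 40 Hz frames each window holds 125 samples.
#'
#' @param pressure Data frame with `time_s` and `pressure_cmH2O`.
#' @param frame_time_s Frame (rotation) start times, seconds.
#' @param frame_rate Frame rate, rotations/s.
#' @return Data frame `frame, time_s, mean_cmH2O, sd_cmH2O, n_samples`.
#' @export
frame_pressure_stats <- function(pressure, frame_time_s, frame_rate) {
  stopifnot(is.data.frame(pressure),
            all(c("time_s", "pressure_cmH2O") %in% names(pressure)),
            frame_rate > 0, length(frame_time_s) >= 1)
  breaks <- c(frame_time_s, frame_time_s[length(frame_time_s)] + 1 / frame_rate)
  bin <- findInterval(pressure$time_s, breaks,
                      left.open = FALSE, rightmost.closed = FALSE)
  inside <- bin >= 1 & bin <= length(frame_time_s) &
    pressure$time_s < breaks[pmin(bin + 1, length(breaks))]
  bin <- bin[inside]
  p <- pressure$pressure_cmH2O[inside]
  n <- tabulate(bin, nbins = length(frame_time_s))
  if (any(n == 0))
    stop("frame_pressure_stats: ", sum(n == 0),
         " frame window(s) contain no pressure samples")
  mu <- as.numeric(tapply(p, factor(bin, levels = seq_along(frame_time_s)),
                          mean))
  sdv <- as.numeric(tapply(p, factor(bin, levels = seq_along(frame_time_s)),
                           stats::sd))
  sdv[is.na(sdv)] <- 0
  data.frame(frame = seq_along(frame_time_s), time_s = frame_time_s,
             mean_cmH2O = mu, sd_cmH2O = sdv, n_samples = n)
}

#' Detect complete respiratory cycles in a frame-synchronous signal
#'
#' Splits a periodic signal (by default the frame-mean pressure; the CSA
#' series is a usable fallback) into complete breath cycles. The signal is
#' smoothed by a short running mean, candidate boundaries are placed at the
#' centres of below-midlevel runs (the expiratory baseline), boundaries
#' closer than half the nominal period are merged, and only intervals
#' containing an above-midlevel excursion count as complete cycles. Cardiac
#' ripple is suppressed by the smoothing and the midlevel prominence
#' requirement.
#'
#' @param x Numeric signal, one value per frame.
#' @param frame_rate Frames per second.
#' @param breaths_per_min Nominal respiratory rate used for the minimum
#'   boundary separation.
#' @param smooth_s Running-mean window, seconds.
#' @param min_range Minimum peak-to-trough range for the signal to count as
#'   modulated (same units as `x`).
#' @return Data frame `start, end` of frame indices (`end` exclusive), one
#'   row per complete cycle, >= 2 rows guaranteed.
#' @export
detect_cycles <- function(x, frame_rate, breaths_per_min = 20,
                          smooth_s = 0.25, min_range = 1e-6) {
  n <- length(x)
  period_frames <- frame_rate * 60 / breaths_per_min
  if (n < 2 * period_frames)
    stop(errorCondition(
      "detect_cycles: signal shorter than two nominal periods",
      class = c("aoctel_rejected", "error", "condition")))
  k <- max(1L, round(smooth_s * frame_rate))
  if (k %% 2 == 0) k <- k + 1L
  s <- stats::filter(x, rep(1 / k, k), sides = 2)
  s <- as.numeric(s); s[is.na(s)] <- x[is.na(s)]
  rng <- max(s) - min(s)
  if (!(rng > min_range))
    stop(errorCondition("detect_cycles: no modulation in signal",
                        class = c("aoctel_rejected", "error", "condition")))
  mid <- (max(s) + min(s)) / 2
  low <- s < mid
  if (!any(low) || all(low))
    stop(errorCondition("detect_cycles: no cycles detected",
                        class = c("aoctel_rejected", "error", "condition")))
  # centres of below-midlevel runs are cycle boundaries
  lab <- cumsum(c(TRUE, diff(low) != 0))
  bounds <- vapply(unique(lab[low]), function(rl)
    round(mean(which(lab == rl & low))), numeric(1))
  bounds <- sort(bounds)
  # merge boundaries closer than half a nominal period
  keep <- rep(TRUE, length(bounds))
  last <- bounds[1]
  for (i in seq_along(bounds)[-1]) {
    if (bounds[i] - last < 0.5 * period_frames) keep[i] <- FALSE
    else last <- bounds[i]
  }
  bounds <- bounds[keep]
  if (length(bounds) < 2)
    stop(errorCondition("detect_cycles: insufficient cycles",
                        class = c("aoctel_rejected", "error", "condition")))
  cyc <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  # a complete cycle must contain an above-midlevel excursion
  has_peak <- vapply(seq_len(nrow(cyc)), function(i)
    any(s[cyc$start[i]:(cyc$end[i] - 1)] > mid), logical(1))
  cyc <- cyc[has_peak, , drop = FALSE]
  if (nrow(cyc) < 2)
    stop(errorCondition("detect_cycles: insufficient cycles (< 2 complete)",
                        class = c("aoctel_rejected", "error", "condition")))
  rownames(cyc) <- NULL
  cyc
}

#' Per-cycle extrema of CSA and frame-mean pressure
#'
#' For each detected cycle, records the maximum and minimum CSA over its
#' frames and, independently, the maximum and minimum frame-mean pressure.
#' Recording the two channels' extrema independently makes the estimate
#' robust to any lag between pressure and CSA inside a cycle. Cycles with
#' fewer than `min_frames` frames are dropped; fewer than 2 surviving cycles
#' is an error.
#'
#' @param csa Numeric CSA per frame, mm^2.
#' @param p_mean Numeric frame-mean pressure per frame, cmH2O.
#' @param cycles Data frame `start, end` from [detect_cycles()].
#' @param min_frames Minimum frames per usable cycle.
#' @return Data frame, one row per cycle: `cycle, max_csa, min_csa, max_p,
#'   min_p, frame_max, frame_min`.
#' @export
cycle_extrema <- function(csa, p_mean, cycles, min_frames = 4) {
  stopifnot(length(csa) == length(p_mean),
            all(c("start", "end") %in% names(cycles)))
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    idx <- cycles$start[i]:(cycles$end[i] - 1)
    if (length(idx) < min_frames) return(NULL)
    data.frame(cycle = i,
               max_csa = max(csa[idx]), min_csa = min(csa[idx]),
               max_p = max(p_mean[idx]), min_p = min(p_mean[idx]),
               frame_max = idx[which.max(csa[idx])],
               frame_min = idx[which.min(csa[idx])])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 2)
    stop(errorCondition("cycle_extrema: fewer than 2 usable cycles",
                        class = c("aoctel_rejected", "error", "condition")))
  out
}

#' Cross-sectional compliance and normalized compliance of a scan
#'
#' Implements the per-scan compliance estimate from cycle extrema:
#' `dCSA = mean(max_csa) - mean(min_csa)`, `dp = mean(max_p) - mean(min_p)`,
#' the time-averaged area `CSA_bar` is the joint mean of all per-cycle maxima
#' and minima, cross-sectional compliance `CC = dCSA / dp` (mm^2/cmH2O), and
#' normalized cross-sectional compliance
#' `nCsC = 100 * (dCSA / CSA_bar) / dp` (%/cmH2O).
#'
#' Uncertainties: for each cycle the standard deviation of CSA is taken over
#' the five frames preceding and following the frame of the maximum
#' (respectively minimum) CSA; per-cycle values are pooled by averaging into
#' `sd_max_csa` and `sd_min_csa`, and the standard deviation of the averaged
#' CSA is their root sum `sd_csa_bar = sqrt(sd_max^2 + sd_min^2)` (with
#' `sd_rule = "sum_of_roots"` the literal sum is used instead). Windows
#' truncated by the scan edge raise a warning.
#'
#' @param extrema Data frame from [cycle_extrema()].
#' @param csa Numeric CSA per frame (the full series, for the +/-5-frame
#'   uncertainty windows).
#' @param sd_window Half-width of the uncertainty window, frames.
#' @param sd_rule `"rss"` (root-sum-of-squares, default) or
#'   `"sum_of_roots"`.
#' @return Object of class `compliance_result` with fields `csa_bar_mm2`,
#'   `d_csa_mm2`, `d_p_cmH2O`, `cc_mm2_per_cmH2O`, `ncsc_pct_per_cmH2O`,
#'   `sd_min_csa`, `sd_max_csa`, `sd_csa_bar`, `n_cycles`.
#' @export
compliance <- function(extrema, csa, sd_window = 5, sd_rule = c("rss", "sum_of_roots")) {
  sd_rule <- match.arg(sd_rule)
  stopifnot(nrow(extrema) >= 2)
  d_csa <- mean(extrema$max_csa) - mean(extrema$min_csa)
  d_p <- mean(extrema$max_p) - mean(extrema$min_p)
  if (!(d_p > 0))
    stop(errorCondition("compliance: no pressure modulation (dp <= 0)",
                        class = c("aoctel_rejected", "error", "condition")))
  csa_bar <- mean(c(extrema$max_csa, extrema$min_csa))
  cc <- d_csa / d_p
  ncsc <- 100 * (d_csa / csa_bar) / d_p
  win_sd <- function(center) {
    lo <- center - sd_window; hi <- center + sd_window
    if (lo < 1 || hi > length(csa)) {
      warning("compliance: uncertainty window truncated at scan edge")
      lo <- max(1, lo); hi <- min(length(csa), hi)
    }
    stats::sd(csa[lo:hi])
  }
  sd_max <- mean(vapply(extrema$frame_max, win_sd, numeric(1)))
  sd_min <- mean(vapply(extrema$frame_min, win_sd, numeric(1)))
  sd_bar <- if (sd_rule == "rss") sqrt(sd_max^2 + sd_min^2) else sd_max + sd_min
  structure(list(csa_bar_mm2 = csa_bar, d_csa_mm2 = d_csa, d_p_cmH2O = d_p,
                 cc_mm2_per_cmH2O = cc, ncsc_pct_per_cmH2O = ncsc,
                 sd_min_csa = sd_min, sd_max_csa = sd_max, sd_csa_bar = sd_bar,
                 n_cycles = nrow(extrema)),
            class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat(sprintf(
    paste0("compliance over %d cycles: CSA_bar = %.3g mm2, dCSA = %.3g mm2, ",
           "dp = %.3g cmH2O\n  CC = %.4g mm2/cmH2O, nCsC = %.4g %%/cmH2O ",
           "(sd CSA max/min/bar = %.2g/%.2g/%.2g mm2)\n"),
    x$n_cycles, x$csa_bar_mm2, x$d_csa_mm2, x$d_p_cmH2O, x$cc_mm2_per_cmH2O,
    x$ncsc_pct_per_cmH2O, x$sd_max_csa, x$sd_min_csa, x$sd_csa_bar))
  invisible(x)
}

#' @export
as.data.frame.compliance_result <- function(x, ...) {
  data.frame(csa_bar_mm2 = x$csa_bar_mm2, d_csa_mm2 = x$d_csa_mm2,
             d_p_cmH2O = x$d_p_cmH2O, cc = x$cc_mm2_per_cmH2O,
             ncsc_pct_per_cmH2O = x$ncsc_pct_per_cmH2O,
             sd_min_csa = x$sd_min_csa, sd_max_csa = x$sd_max_csa,
             sd_csa_bar = x$sd_csa_bar, n_cycles = x$n_cycles)
}

#' Compliance of a scan from its CSA series and pressure trace
#'
#' Convenience wrapper chaining [frame_pressure_stats()], [detect_cycles()],
#' [cycle_extrema()] and [compliance()].
#'
#' @param csa_series A `csa_series` from [segment_stack()], or a data frame
#'   `frame, time_s, csa_mm2`.
#' @param pressure Data frame `time_s, pressure_cmH2O`.
#' @param frame_rate Frame rate, Hz.
#' @param breaths_per_min Nominal respiratory rate hint.
#' @param ... Passed to [compliance()].
#' @return A `compliance_result`.
#' @export
scan_compliance <- function(csa_series, pressure, frame_rate = 40,
                            breaths_per_min = 20, ...) {
  csa_df <- if (inherits(csa_series, "csa_series")) csa_series$csa
            else csa_series
  fp <- frame_pressure_stats(pressure, csa_df$time_s, frame_rate)
  cyc <- detect_cycles(fp$mean_cmH2O, frame_rate, breaths_per_min)
  ext <- cycle_extrema(csa_df$csa_mm2, fp$mean_cmH2O, cyc)
  compliance(ext, csa_df$csa_mm2, ...)
}
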