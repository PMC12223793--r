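#' Detect the catheter sheath's outer radius in a polar frame
#'
#' Averages the linear intensity over all angular columns and locates the
#' bright near-axis ring produced by the sheath. Its outer (deeper) edge is
#' returned in pixels, with a sub-pixel fraction recovered from the
#' partial-volume intensity of the edge pixel (the ring is the calibration
#' target, so quantizing its radius to whole pixels would leak directly into
#' the area scale). The search is restricted to the first `search_frac` of
#' the depth axis.
#'
#' @param frame Matrix `depth_px x n_angles` of dB intensities.
#' @param geom A [scan_geometry()].
#' @param rise_db Detection threshold above the background median, dB.
#' @param search_frac Fraction of the depth axis searched for the ring.
#' @return Sheath outer radius in pixels (scalar, sub-pixel).
#' @export
detect_sheath <- function(frame, geom = scan_geometry(), rise_db = 20,
                          search_frac = 0.25) {
  stopifnot(is.matrix(frame))
  # compensate the documented sensitivity roll-off so the ring profile is
  # flat and its partial-volume edge interpolates without bias
  z <- (seq_len(nrow(frame)) - 0.5) * mm_per_px(geom)
  prof <- rowMeans(10^(frame / 10)) / rolloff_amp(z)^2
  n_search <- max(2L, floor(search_frac * length(prof)))
  floor_int <- stats::median(prof[seq_len(n_search)])
  search <- prof[seq_len(n_search)]
  if (max(search) < floor_int * 10^(rise_db / 10))
    stop(errorCondition("detect_sheath: sheath not detected",
                        class = c("aoctel_rejected", "error", "condition")))
  level <- max(search)
  bright <- which(search >= level / 2)
  gaps <- which(diff(bright) > 1)      # first contiguous bright ring
  if (length(gaps)) bright <- bright[seq_len(gaps[1])]
  e0 <- bright[length(bright)]         # last row with >= half coverage
  # partial-volume edge: the summed coverage of the half-covered row and its
  # successor places the ring edge to sub-pixel precision
  nxt <- if (e0 < length(prof)) prof[e0 + 1] else floor_int
  frac <- (prof[e0] + nxt - 2 * floor_int) / (level - floor_int)
  e0 - 1 + max(0, min(1.5, frac))
}

#' Pixel-scale calibration from the detected sheath radius
#'
#' The sheath outer diameter is a physical constant (`geom$sheath_od_mm`),
#' so the millimetre-per-pixel scale of a scan is fixed by requiring the
#' detected sheath radius to equal `sheath_od_mm / 2`. This compensates
#' reference-arm length variation between scans.
#'
#' @param detected_sheath_px Sheath outer radius in pixels.
#' @param geom A [scan_geometry()].
#' @return Scale in mm per pixel.
#' @export
calibrate_scale <- function(detected_sheath_px, geom = scan_geometry()) {
  stopifnot(length(detected_sheath_px) == 1, detected_sheath_px > 0)
  (geom$sheath_od_mm / 2) / detected_sheath_px
}

# first/last index of TRUE per column of a logical matrix (NA when none)
.col_first_true <- function(m) {
  idx <- max.col(t(m), ties.method = "first")
  idx[!m[cbind(idx, seq_len(ncol(m)))]] <- NA_integer_
  idx
}

.col_last_true <- function(m) {
  idx <- max.col(t(m), ties.method = "last")
  idx[!m[cbind(idx, seq_len(ncol(m)))]] <- NA_integer_
  idx
}

# circular running median (binary input => circular majority vote)
circular_runmed <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n < 2 * k) return(x)
  half <- k %/% 2
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  y <- stats::runmed(xx, k, endrule = "keep")
  y[(half + 1):(half + n)]
}

# circular running mean (recovers sub-pixel smoothness after the median)
circular_runmean <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n < 2 * k) return(x)
  half <- k %/% 2
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  y <- as.numeric(stats::filter(xx, rep(1 / k, k), sides = 2))
  out <- y[(half + 1):(half + n)]
  out[is.na(out)] <- x[is.na(out)]
  out
}

# circular linear interpolation over NA gaps in a periodic signal
circular_fill <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == n || length(ok) == 0) return(x)
  idx <- c(ok, ok + n)
  val <- c(x[ok], x[ok])
  out <- stats::approx(idx, val, xout = seq_len(n) + n, rule = 2)$y
  x[is.na(x)] <- out[is.na(x)]
  x
}

# Edge-position refinement.
# sm_int: depth-smoothed intensity; raw_int: unsmoothed intensity;
# cols/i0: per-column raw edge rows. A coarse position comes from the
# half-crossing of the local smoothed maximum (the surface is the brightest
# point of the attenuation-decaying band); it is then snapped to the largest
# neighbouring-pixel ratio nearby, which is exact on clean frames and keeps
# the smoothing/attenuation bias out. side "rise": air-to-tissue edge;
# side "fall": the deep edge of a band mirrored by fold-over.
# Returns a continuous radius estimate in px.
.refine_edge <- function(sm_int, cols, i0, smooth_px, side = "rise",
                         raw_int = sm_int) {
  depth <- nrow(sm_int)
  out <- rep(NA_real_, length(cols))
  xmin <- .Machine$double.xmin
  for (j in seq_along(cols)) {
    c0 <- cols[j]; r0 <- i0[j]
    if (is.na(r0)) next
    win <- max(1, r0 - smooth_px):min(depth, r0 + smooth_px)
    ref <- max(sm_int[win, c0])
    hit <- win[sm_int[win, c0] >= ref / 2]
    if (side == "rise") {
      h <- if (length(hit)) hit[1] else r0
      snap <- max(2, h - 2):min(depth, h + 2)
      s0 <- snap[which.max(raw_int[snap, c0] /
                             pmax(raw_int[snap - 1, c0], xmin))]
      out[j] <- s0 - 1
    } else {
      h <- if (length(hit)) hit[length(hit)] else r0
      snap <- max(1, h - 2):min(depth - 1, h + 2)
      e0 <- snap[which.max(raw_int[snap, c0] /
                             pmax(raw_int[snap + 1, c0], xmin))]
      out[j] <- e0
    }
  }
  out
}

#' Segment the air--tissue interface in one polar frame
#'
#' Per angular column the detector finds sustained rises of the
#' depth-smoothed intensity above an adaptive threshold (background median
#' plus `rise_db`), beyond the sheath. Columns split into three regimes:
#'
#' * ordinary columns: the surface is the first rise, refined to the
#'   half-intensity crossing of the band edge;
#' * fold-over columns: when the deep edge of the detected band is brighter
#'   than its shallow edge (intensity increasing with depth, the signature of
#'   a band mirrored about the maximum imaging depth), the column is flagged
#'   aliased and the deeper edge is taken as the surface -- the "lower
#'   surface preferred" rule;
#' * bottom-contact columns (brightness reaching within `bottom_margin`
#'   pixels of the bottom row): if the unsmoothed intensity is bright down to
#'   the very bottom row, the direct band has merged with the mirrored tail
#'   of the wall and the surface is the deepest significant intensity step
#'   (ratio `step_ratio` between neighbouring pixels); otherwise the bright
#'   region stops just short of the bottom, which identifies a fold surface
#'   near the maximum depth (flagged aliased, deepest bright pixel taken).
#'
#' Aliased flags are majority-smoothed circularly and the surface is smoothed
#' by a circular running median over `median_window` columns. Columns with no
#' detectable surface or with tissue touching the sheath are invalid; if more
#' than `max_missing_frac` of columns are invalid the scan is rejected as
#' unusable (condition class `aoctel_rejected`).
#'
#' Optional `seed_depths` stand in for the manual input of a semi-automatic
#' workflow: candidate surfaces further than `seed_tol_px` from the per-column
#' seed are ignored.
#'
#' @param frame Matrix `depth_px x n_angles` of dB intensities.
#' @param geom A [scan_geometry()].
#' @param sheath_px Sheath outer radius in pixels (detected if `NULL`).
#' @param rise_db Threshold above background median, dB.
#' @param smooth_px Depth boxcar window, pixels (odd).
#' @param run_px Sustained-rise run length, pixels.
#' @param median_window Circular median window across columns (odd).
#' @param bottom_margin Bottom-contact margin, pixels.
#' @param step_ratio Neighbour-intensity ratio marking a significant step in
#'   bottom-contact columns.
#' @param max_missing_frac Maximum tolerated fraction of invalid columns.
#' @param seed_depths Optional numeric vector (`n_angles`) of approximate
#'   surface depths in pixels.
#' @param seed_tol_px Tolerance around seed depths, pixels.
#' @return A list of class `lumen_segmentation`: `surface_px` (per-column
#'   apparent surface radius in pixels, NA where invalid), `aliased` (fold
#'   flags), `bottom` (bottom-contact flags), `valid`, `sheath_px`.
#' @export
segment_lumen <- function(frame, geom = scan_geometry(), sheath_px = NULL,
                          rise_db = 15, smooth_px = 7, run_px = 3,
                          median_window = 25, bottom_margin = 3,
                          step_ratio = 1.5, max_missing_frac = 0.5,
                          seed_depths = NULL, seed_tol_px = 40) {
  stopifnot(is.matrix(frame))
  if (nrow(frame) != geom$depth_px || ncol(frame) != geom$n_angles)
    stop("segment_lumen: frame dimensions do not match geometry")
  depth <- nrow(frame); nang <- ncol(frame)
  if (is.null(sheath_px)) sheath_px <- detect_sheath(frame, geom)
  shf <- min(depth, floor(sheath_px) + run_px + 2)

  inten <- 10^(frame / 10)
  sm <- stats::filter(inten, rep(1 / smooth_px, smooth_px), sides = 2)
  sm <- matrix(as.numeric(sm), nrow(inten), ncol(inten))
  sm[is.na(sm)] <- inten[is.na(sm)]
  smdb <- 10 * log10(pmax(sm, .Machine$double.xmin))

  th <- stats::median(smdb[shf:depth, ]) + rise_db
  above <- smdb >= th
  above[seq_len(shf), ] <- FALSE
  if (!is.null(seed_depths)) {
    stopifnot(length(seed_depths) == nang)
    rows <- matrix(seq_len(depth), depth, nang)
    seedm <- matrix(seed_depths, depth, nang, byrow = TRUE)
    above <- above & (is.na(seedm) | abs(rows - seedm) <= seed_tol_px)
  }
  runs <- above
  if (run_px > 1)
    for (s in seq_len(run_px - 1))
      runs <- runs & rbind(above[-seq_len(s), , drop = FALSE],
                           matrix(FALSE, s, nang))
  first_rise <- .col_first_true(runs)
  last_fall <- .col_last_true(runs) + run_px - 1L
  valid <- !is.na(first_rise)
  bottom <- valid & !is.na(last_fall) & last_fall >= depth - bottom_margin

  # fold orientation: deep band edge brighter than shallow band edge
  aliased <- rep(FALSE, nang)
  ord <- which(valid & !bottom)
  if (length(ord)) {
    top_db <- smdb[cbind(pmin(first_rise[ord] + smooth_px, depth), ord)]
    bot_db <- smdb[cbind(pmax(last_fall[ord] - smooth_px, 1L), ord)]
    sep <- last_fall[ord] - first_rise[ord] > 2 * smooth_px
    aliased[ord] <- sep & (bot_db - top_db > 0)
  }
  surface <- rep(NA_real_, nang)
  bot_cols <- which(bottom)
  if (length(bot_cols)) {
    th_int <- 10^(th / 10)
    raw_above <- inten[, bot_cols, drop = FALSE] >= th_int
    raw_above[seq_len(shf), ] <- FALSE
    tail_rows <- (depth - bottom_margin):depth
    # truly bright down to the bottom row: direct band (possibly merged with
    # a mirrored wall tail); otherwise the surface is a fold just short of
    # the bottom, pushed there only by the depth smoothing
    strict <- colSums(!raw_above[tail_rows, , drop = FALSE]) == 0
    if (any(strict)) {
      cols <- bot_cols[strict]
      xmin <- .Machine$double.xmin
      # does the frame carry speckle? fully developed speckle makes ~1/3 of
      # neighbouring bright-pixel ratios exceed 2; a clean frame almost none
      sub <- seq(1, nang, by = max(1L, nang %/% 64L))
      bb <- inten[(shf + 1):depth, sub, drop = FALSE] >= th_int
      pair <- bb[-1, , drop = FALSE] & bb[-nrow(bb), , drop = FALSE]
      rat2 <- inten[(shf + 2):depth, sub, drop = FALSE] >
        2 * inten[(shf + 1):(depth - 1), sub, drop = FALSE]
      speckled <- sum(pair) > 0 && mean(rat2[pair]) > 0.1
      if (speckled) {
        # speckle drowns single-pixel ratios; use the boxcar-smoothed
        # intensity and demand a large step over smooth_px rows (the
        # direct-surface step over the mirrored haze is >= ~15 dB except in
        # a narrow zone right at the fold)
        gs <- smooth_px
        rr <- sm[(gs + 1):depth, cols, drop = FALSE] /
          pmax(sm[seq_len(depth - gs), cols, drop = FALSE], xmin)
        qual <- rr >= 8 & sm[(gs + 1):depth, cols, drop = FALSE] >= th_int
        qual[seq_len(min(shf, nrow(qual))), ] <- FALSE
        deepest <- .col_last_true(qual)
        for (j in seq_along(cols)) {
          c0 <- cols[j]; i0 <- deepest[j]
          if (is.na(i0)) {              # no sharp edge: fold at maximum depth
            surface[c0] <- depth
            aliased[c0] <- TRUE
          } else {                      # edge within [i0, i0 + gs]
            win <- max(2, i0):min(depth, i0 + 2 * gs)
            r1 <- inten[win, c0] / pmax(inten[win - 1, c0], xmin)
            surface[c0] <- win[which.max(r1)] - 1
          }
        }
      } else {
        ri <- inten[2:depth, cols, drop = FALSE] /
          pmax(inten[seq_len(depth - 1), cols, drop = FALSE], xmin)
        qual <- ri >= step_ratio &
          inten[2:depth, cols, drop = FALSE] >= th_int
        qual[seq_len(min(shf, nrow(qual))), ] <- FALSE
        deepest <- .col_last_true(qual) + 1L
        no_edge <- is.na(deepest)
        surface[cols] <- deepest - 1
        surface[cols[no_edge]] <- depth
        aliased[cols[no_edge]] <- TRUE
      }
    }
    if (any(!strict)) {
      cols <- bot_cols[!strict]
      e0 <- .col_last_true(raw_above[, !strict, drop = FALSE])
      e0 <- ifelse(is.na(e0), last_fall[cols], e0)
      # a fold brightens toward its deep edge; an attenuated direct band
      # that merely peters out near the bottom dims instead
      deep_db <- shallow_db <- numeric(length(cols))
      for (j in seq_along(cols)) {
        hi <- max(2 * smooth_px + 1, e0[j])
        deep_db[j] <- mean(smdb[(hi - smooth_px + 1):hi, cols[j]])
        shallow_db[j] <- mean(smdb[max(1, hi - 3 * smooth_px + 1):
                                     (hi - 2 * smooth_px), cols[j]])
      }
      fold <- deep_db > shallow_db
      fc <- cols[fold]
      surface[fc] <- e0[fold]
      aliased[fc] <- TRUE
      dc <- cols[!fold]
      if (length(dc))
        surface[dc] <- .refine_edge(sm, dc, first_rise[dc], smooth_px,
                                    "rise", raw_int = inten)
    }
  }
  aliased <- circular_runmed(as.numeric(aliased), median_window) > 0.5
  aliased[!valid] <- FALSE
  dir_cols <- which(valid & !bottom & !aliased)
  if (length(dir_cols))
    surface[dir_cols] <- .refine_edge(sm, dir_cols, first_rise[dir_cols],
                                      smooth_px, "rise", raw_int = inten)
  ali_cols <- which(valid & !bottom & aliased)
  if (length(ali_cols))
    surface[ali_cols] <- .refine_edge(sm, ali_cols, last_fall[ali_cols],
                                      smooth_px, "fall", raw_int = inten)

  contact <- valid & !is.na(surface) & surface <= sheath_px + run_px + 2
  valid <- valid & !contact
  surface[!valid] <- NA
  if (mean(!valid) > max_missing_frac)
    stop(errorCondition(sprintf(
      "segment_lumen: scan unusable, %.0f%% of columns have no usable surface",
      100 * mean(!valid)),
      class = c("aoctel_rejected", "error", "condition")))
  # smooth in the corrected (unfolded) domain, where the boundary has no
  # kink at the fold junction, then map back to apparent depths
  tmp <- surface
  tmp[aliased] <- 2 * depth - tmp[aliased]
  tmp <- circular_runmed(circular_fill(tmp), median_window)
  tmp <- circular_runmean(tmp, max(3L, smooth_px))
  tmp[aliased] <- 2 * depth - tmp[aliased]
  filled <- tmp
  filled[!valid] <- NA
  structure(list(surface_px = filled, aliased = aliased, bottom = bottom,
                 valid = valid, sheath_px = sheath_px),
            class = "lumen_segmentation")
}

#' Mirror-correct fold-over aliasing in a segmented surface
#'
#' Within each flagged contiguous run of columns the apparent surface is
#' mirrored about the maximum imaging depth, `r_corrected = 2 * depth_px -
#' r_apparent`, undoing how aliasing flips structures beyond the working
#' distance. Each flagged run must be bounded by columns whose surface
#' reaches within `bottom_margin + slack` pixels of the bottom row (or that
#' already exceed it). The mapping is an involution: applying it twice
#' restores the input.
#'
#' @param surface_px Per-column apparent surface radius, pixels.
#' @param flags Logical per-column fold flags (from [segment_lumen()]).
#' @param geom A [scan_geometry()].
#' @param bottom_margin Bottom-contact margin used at run edges, pixels.
#' @param slack Extra edge tolerance after median smoothing, pixels.
#' @return Corrected surface radii; values in flagged runs may exceed
#'   `depth_px` (up to `2 * depth_px`).
#' @export
correct_aliasing <- function(surface_px, flags, geom = scan_geometry(),
                             bottom_margin = 3, slack = 7) {
  n <- length(surface_px)
  stopifnot(length(flags) == n)
  if (!any(flags)) return(surface_px)
  depth <- geom$depth_px
  lab <- cumsum(c(TRUE, diff(flags) != 0))
  if (flags[1] == flags[n]) lab[lab == lab[n]] <- lab[1]
  for (rl in unique(lab[flags])) {
    cols <- which(lab == rl & flags)
    if (length(cols) < n) {
      edges <- surface_px[c(cols[1], cols[length(cols)])]
      if (any(is.na(edges)) ||
          any(edges < depth - (bottom_margin + slack) & edges <= depth))
        stop("correct_aliasing: inconsistent fold region, flagged run not ",
             "bounded by bottom-touching columns")
    }
  }
  out <- surface_px
  out[flags] <- 2 * depth - surface_px[flags]
  out
}

#' Cross-sectional area of a star-shaped polar boundary
#'
#' Computes the polygon area of a closed contour given as radii from the
#' catheter axis at uniformly spaced angles:
#' `A = 1/2 * sum_j r_j r_{j+1} sin(dtheta)`.
#' Invalid (NA) columns are filled by circular linear interpolation first;
#' fewer than 3 valid columns is an error. The result is independent of the
#' axis position as long as the boundary is star-shaped about it.
#'
#' @param radius_mm Per-column boundary radii from the axis, mm (NA allowed).
#' @param n_angles Number of uniformly spaced columns (defaults to
#'   `length(radius_mm)`).
#' @return Area in mm^2.
#' @examples
#' boundary_to_csa(rep(10, 1248))  # ~ pi * 100
#' @export
boundary_to_csa <- function(radius_mm, n_angles = length(radius_mm)) {
  if (sum(!is.na(radius_mm)) < 3)
    stop("boundary_to_csa: fewer than 3 valid columns")
  r <- circular_fill(radius_mm)
  rnext <- c(r[-1], r[1])
  0.5 * sum(r * rnext * sin(2 * pi / n_angles))
}

#' Segment a whole frame stack into a calibrated CSA time series
#'
#' Runs [detect_sheath()] (median over up to `sheath_frames` frames),
#' [calibrate_scale()], [segment_lumen()] and [correct_aliasing()] on every
#' frame, converts the corrected surface to millimetres from the axis, and
#' integrates each frame's boundary into a cross-sectional area.
#'
#' @param stack Array `depth_px x n_angles x n_frames` of dB intensities,
#'   optionally with a `time_s` attribute (as from [render_frames()] or
#'   [read_frames_tiff()]); frame times default to `frame_times(geom)`.
#' @param geom A [scan_geometry()].
#' @param sheath_frames Number of frames used for sheath calibration.
#' @param seed_matrix Optional `n_frames x n_angles` matrix of approximate
#'   surface depths in pixels (NA allowed), the stand-in for semi-automatic
#'   seeding; row `f` is passed to [segment_lumen()] as its `seed_depths`.
#' @param ... Passed to [segment_lumen()].
#' @return List of class `csa_series`: `csa` data frame
#'   (`frame, time_s, csa_mm2`), `scale_mm_per_px`, `sheath_px`,
#'   `boundary_mm` (`n_frames x n_angles`), `aliased` (logical matrix).
#' @export
segment_stack <- function(stack, geom = scan_geometry(), sheath_frames = 5,
                          seed_matrix = NULL, ...) {
  stopifnot(length(dim(stack)) == 3)
  if (!is.null(seed_matrix))
    stopifnot(nrow(seed_matrix) >= dim(stack)[3],
              ncol(seed_matrix) == geom$n_angles)
  nf <- dim(stack)[3]
  times <- attr(stack, "time_s")
  if (is.null(times)) times <- frame_times(geom)
  sp <- stats::median(vapply(seq_len(min(sheath_frames, nf)), function(f)
    detect_sheath(stack[, , f], geom), numeric(1)))
  scale <- calibrate_scale(sp, geom)
  boundary <- matrix(NA_real_, nf, geom$n_angles)
  aliased <- matrix(FALSE, nf, geom$n_angles)
  csa <- numeric(nf)
  for (f in seq_len(nf)) {
    seg <- segment_lumen(stack[, , f], geom, sheath_px = sp,
                         seed_depths = if (is.null(seed_matrix)) NULL
                                       else seed_matrix[f, ], ...)
    corr <- correct_aliasing(seg$surface_px, seg$aliased, geom)
    boundary[f, ] <- corr * scale
    aliased[f, ] <- seg$aliased
    csa[f] <- boundary_to_csa(boundary[f, ])
  }
  structure(list(csa = data.frame(frame = seq_len(nf),
                                  time_s = times[seq_len(nf)],
                                  csa_mm2 = csa),
                 scale_mm_per_px = scale, sheath_px = sp,
                 boundary_mm = boundary, aliased = aliased),
            class = "csa_series")
}

#' @export
print.csa_series <- function(x, ...) {
  cat(sprintf(
    "CSA series: %d frames, CSA %.3g-%.3g mm2, scale %.4g mm/px (sheath %.1f px)\n",
    nrow(x$csa), min(x$csa$csa_mm2), max(x$csa$csa_mm2), x$scale_mm_per_px,
    x$sheath_px))
  invisible(x)
}
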