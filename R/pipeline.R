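#' Generate a complete synthetic scan on disk
#'
#' Runs the simulator end to end — ventilator pressure, ground-truth
#' boundary of the elastic tube, rendered polar frames — and writes the
#' artifacts a real acquisition would provide (TIFF stack + JSON sidecar,
#' pressure CSV) together with the ground truth (CSA CSV, nCsC/tube JSON).
#'
#' @param out_dir Output directory (created if needed).
#' @param geom A [scan_geometry()].
#' @param tube A [tube_model()].
#' @param vent A [ventilator_params()].
#' @param catheter_offset_mm Length-2 catheter offset, mm.
#' @param seed Integer seed covering pressure noise and speckle.
#' @param speckle Render speckle/noise (TRUE) or noiseless frames.
#' @param apparent_scale Reference-arm mismatch factor for the renderer.
#' @param stack_name Base name of the TIFF stack.
#' @return Invisibly, a list with the ground truth (`gt`) and the written
#'   paths (`stack`, `pressure`, `truth_csv`, `truth_json`).
#' @export
synth_scan <- function(out_dir, geom = scan_geometry(), tube = tube_model(),
                       vent = ventilator_params(), catheter_offset_mm = c(0, 0),
                       seed = 1, speckle = TRUE, apparent_scale = 1,
                       stack_name = "stack.tif") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pressure <- make_pressure(vent, geom, seed = seed)
  gt <- simulate_boundary(tube, pressure, geom,
                          catheter_offset_mm = catheter_offset_mm,
                          cardiac_amp = vent$cardiac_amp,
                          cardiac_hz = vent$cardiac_hz)
  stack <- render_frames(gt, geom, speckle = speckle,
                         apparent_scale = apparent_scale, seed = seed + 1L)
  paths <- list(stack = file.path(out_dir, stack_name),
                pressure = file.path(out_dir, "pressure.csv"),
                truth_csv = file.path(out_dir, "truth_csa.csv"),
                truth_json = file.path(out_dir, "truth.json"))
  write_frames_tiff(stack, paths$stack, geom)
  write_pressure_csv(pressure, paths$pressure)
  write_ground_truth(gt, paths$truth_csv, paths$truth_json)
  invisible(c(list(gt = gt), paths))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.geom_from_config <- function(config, fallback = NULL) {
  g <- config$geometry
  if (is.null(g)) return(if (is.null(fallback)) scan_geometry() else fallback)
  base <- if (is.null(fallback)) formals(scan_geometry) else unclass(fallback)
  args <- utils::modifyList(as.list(base), g)
  do.call(scan_geometry, args[names(formals(scan_geometry))])
}

#' Run the full single-scan pipeline from a configuration
#'
#' Reads a frame stack and pressure trace, segments every frame, computes
#' compliance, and writes `boundary.csv`, `csa.csv`, `result.csv` and a
#' reproducibility manifest (`manifest.json` with package version, seed and
#' config hash) to the output directory. Deterministic: identical config and
#' seed reproduce byte-identical result files.
#'
#' @param config A list or path to a YAML file with fields:
#'   `paths$stack` (TIFF from [write_frames_tiff()] or [synth_scan()]),
#'   `paths$pressure` (CSV), `paths$out_dir`; optional `scan_id`,
#'   `geometry` overrides, `segmentation` (arguments of [segment_lumen()]),
#'   `cycles$breaths_per_min`, `sd_rule`, `seed`.
#' @return Invisibly, a list with `result` (a `compliance_result`), `series`
#'   (the `csa_series`) and the written paths.
#' @export
run_scan <- function(config) {
  config <- .load_config(config)
  p <- config$paths
  for (f in c("stack", "pressure"))
    if (is.null(p[[f]]) || !file.exists(p[[f]]))
      stop("run_scan: missing input file for '", f, "': ",
           if (is.null(p[[f]])) "(not set)" else p[[f]])
  out_dir <- p$out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scan_id <- config$scan_id %||% "scan"
  stack <- read_frames_tiff(p$stack)
  geom <- .geom_from_config(config, attr(stack, "geometry"))
  pressure <- read_pressure_csv(p$pressure)
  seg_args <- config$segmentation %||% list()
  if (!is.null(p$seeds))
    seg_args$seed_matrix <- read_seed_csv(p$seeds, dim(stack)[3],
                                          geom$n_angles)
  series <- do.call(segment_stack, c(list(stack = stack, geom = geom),
                                     seg_args))
  bpm <- config$cycles$breaths_per_min %||% 20
  res <- scan_compliance(series, pressure, frame_rate = geom$frame_rate,
                         breaths_per_min = bpm,
                         sd_rule = config$sd_rule %||% "rss")
  out <- cbind(data.frame(scan_id = scan_id), as.data.frame(res))
  paths <- list(boundary = file.path(out_dir, "boundary.csv"),
                csa = file.path(out_dir, "csa.csv"),
                result = file.path(out_dir, "result.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_boundary_csv(series, paths$boundary)
  write_csa_csv(series, paths$csa)
  utils::write.csv(out, paths$result, row.names = FALSE, quote = FALSE)
  manifest <- list(package = "aoctel",
                   version = as.character(utils::packageVersion("aoctel")),
                   seed = config$seed %||% NA,
                   config_hash = .config_hash(config),
                   scan_id = scan_id,
                   n_frames = nrow(series$csa),
                   n_cycles = res$n_cycles)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(result = res, series = series, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a multi-scan study: per-scan compliance plus study-level statistics
#'
#' Processes every scan listed in the configuration with [run_scan()], joins
#' the per-scan nCsC values with the metadata CSV
#' (`scan_id,intensity,time_label,position`), encodes covariates, and writes
#' the study table plus tidy ANOVA and regression reports (and, when a
#' histology CSV `slide_id,intensity,position,grade` is given, the
#' grade-on-intensity/position reports). Optionally draws an nCsC summary
#' plot (nCsC versus time, colored by intensity, panelled by position bin).
#'
#' @param config A list or YAML path with `scans` (list of per-scan configs
#'   as for [run_scan()]), `metadata` (CSV path), optional `histology` (CSV
#'   path), `out_dir`, `anova$terms`, `anova$ss_type`, `plot` (logical).
#' @return Invisibly, a list with `study` (the joined table), `anova`,
#'   `regression`, and (if requested) `histology_anova`,
#'   `histology_regression`.
#' @export
run_study <- function(config) {
  config <- .load_config(config)
  scans <- config$scans
  if (is.null(scans) || length(scans) < 2)
    stop("run_study: need at least 2 scans")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- lapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    sc$paths$out_dir <- sc$paths$out_dir %||%
      file.path(out_dir, sprintf("scan_%03d", i))
    r <- tryCatch(run_scan(sc), error = function(e) {
      stop("run_study: scan '", sc$scan_id %||% i, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    cbind(data.frame(scan_id = sc$scan_id %||% sprintf("scan_%03d", i)),
          as.data.frame(r$result))
  })
  results <- do.call(rbind, results)
  meta <- utils::read.csv(config$metadata)
  missing_ids <- setdiff(results$scan_id, meta$scan_id)
  extra_ids <- setdiff(meta$scan_id, results$scan_id)
  if (length(missing_ids))
    stop("run_study: metadata missing scan ids: ",
         paste(missing_ids, collapse = ", "))
  if (length(extra_ids))
    warning("run_study: metadata rows without scans: ",
            paste(extra_ids, collapse = ", "))
  meta <- encode_covariates(meta)
  study <- merge(results, meta, by = "scan_id", sort = TRUE)
  study <- study[order(study$scan_id), ]
  study$ncsc <- study$ncsc_pct_per_cmH2O
  terms <- config$anova$terms %||% c("intensity", "time", "position",
                                     "intensity:time", "intensity:position",
                                     "time:position",
                                     "intensity:time:position")
  ss_type <- config$anova$ss_type %||% 2
  av <- anova_ncsc(study, terms = terms, ss_type = ss_type)
  rg <- regress(study, "ncsc", c("intensity", "time", "position"))
  utils::write.csv(study, file.path(out_dir, "study_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(av), file.path(out_dir, "anova_ncsc.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(rg),
                   file.path(out_dir, "regression_ncsc.csv"),
                   row.names = FALSE, quote = FALSE)
  out <- list(study = study, anova = av, regression = rg)
  if (!is.null(config$histology)) {
    hist_df <- utils::read.csv(config$histology)
    hist_df$intensity <- vapply(hist_df$intensity, encode_intensity,
                                numeric(1))
    hav <- anova_ncsc(hist_df, terms = c("intensity", "position"),
                      response = "grade", ss_type = ss_type)
    hrg <- regress(hist_df, "grade", c("intensity", "position"))
    utils::write.csv(as.data.frame(hav),
                     file.path(out_dir, "anova_grade.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(hrg),
                     file.path(out_dir, "regression_grade.csv"),
                     row.names = FALSE, quote = FALSE)
    out$histology_anova <- hav
    out$histology_regression <- hrg
  }
  if (isTRUE(config$plot)) {
    grDevices::png(file.path(out_dir, "ncsc_summary.png"),
                   width = 900, height = 400)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_study(study)
  }
  invisible(out)
}

#' Summary plot of nCsC against time, intensity and position
#'
#' One panel per position bin (distal/mid/proximal thirds), nCsC versus time
#' with one line per steam intensity level.
#'
#' @param study Data frame with `ncsc`, `time`, `intensity`, `position`.
#' @export
plot_study <- function(study) {
  bins <- cut(study$position, c(-0.01, 1 / 3, 2 / 3, 1.01),
              labels = c("distal (carina)", "mid-trachea",
                         "proximal (larynx)"))
  op <- graphics::par(mfrow = c(1, nlevels(bins)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c("#1b9e77", "#d95f02", "#7570b3")
  for (b in levels(bins)) {
    d <- study[bins == b, ]
    plot(NA, xlim = range(study$time), ylim = range(study$ncsc),
         xlab = "time post-injury (h)", ylab = "nCsC (%/cmH2O)", main = b)
    for (k in sort(unique(d$intensity))) {
      dd <- d[d$intensity == k, ]
      dd <- dd[order(dd$time), ]
      graphics::lines(dd$time, dd$ncsc, type = "b", col = cols[k], pch = 19)
    }
    graphics::legend("topright", legend = paste("intensity",
                                                sort(unique(d$intensity))),
                     col = cols[sort(unique(d$intensity))], lty = 1, pch = 19,
                     cex = 0.8)
  }
  invisible(NULL)
}
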