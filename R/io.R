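# Minimal multi-page TIFF support (uncompressed, 16-bit grayscale,
# little-endian, one strip per page). No TIFF reader/writer for R is
# available in this stack, so the subset needed for frame stacks is
# implemented here; read_frames_tiff() rejects anything fancier.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_bytes = 279L, sample_format = 339L)

#' Write a frame stack as a multi-page 16-bit grayscale TIFF
#'
#' dB intensities are quantized to uint16 through the affine map
#' `stored = round((db - db_offset) / db_gain)`; the mapping and the scan
#' geometry/timestamps go to a JSON sidecar (same path with extension
#' `.json`) so the stack is self-describing.
#'
#' @param stack Array `depth_px x n_angles x n_frames` of dB values, with
#'   optional `time_s` attribute.
#' @param path Output TIFF path.
#' @param geom A [scan_geometry()].
#' @param db_offset,db_gain Quantization intercept (dB) and step (dB/unit).
#' @return `path`, invisibly. Sidecar written alongside.
#' @export
write_frames_tiff <- function(stack, path, geom, db_offset = -140,
                              db_gain = 0.005) {
  stopifnot(length(dim(stack)) == 3)
  d <- dim(stack)
  q <- round((stack - db_offset) / db_gain)
  q[q < 0] <- 0; q[q > 65535] <- 65535
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  n_entries <- length(TIFF_TAGS)
  ifd_size <- 2 + n_entries * 12 + 4
  page_bytes <- 2 * d[1] * d[2]
  # layout per page: [pixel data][IFD]
  data_off <- 8
  for (f in seq_len(d[3])) {
    ifd_off <- data_off + page_bytes
    next_ifd <- if (f < d[3]) ifd_off + ifd_size + page_bytes else 0L
    # header slot 4..8 or previous IFD's next pointer already written
    if (f == 1) writeBin(as.integer(data_off + page_bytes), con, size = 4,
                         endian = "little")
    writeBin(as.integer(t(q[, , f])), con, size = 2, endian = "little")
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3) {  # SHORT padded to 4 bytes
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else writeBin(as.integer(value), con, size = 4, endian = "little")
    }
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    entry(256, 4, 1, d[2])            # ImageWidth = n_angles
    entry(257, 4, 1, d[1])            # ImageLength = depth_px
    entry(258, 3, 1, 16)              # BitsPerSample
    entry(259, 3, 1, 1)               # Compression: none
    entry(262, 3, 1, 1)               # Photometric: BlackIsZero
    entry(273, 4, 1, data_off)        # StripOffsets
    entry(278, 4, 1, d[1])            # RowsPerStrip
    entry(279, 4, 1, page_bytes)      # StripByteCounts
    entry(339, 3, 1, 1)               # SampleFormat: unsigned int
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    data_off <- ifd_off + ifd_size
  }
  times <- attr(stack, "time_s")
  if (is.null(times)) times <- frame_times(geom)
  side <- list(geometry = unclass(geom), time_s = times,
               db_offset = db_offset, db_gain = db_gain,
               n_frames = d[3])
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[Tt][Ii][Ff]+$", ".json", path)

#' Read a frame stack written by [write_frames_tiff()]
#'
#' Parses the uncompressed 16-bit grayscale multi-page TIFF subset and the
#' JSON sidecar, returning dB values and attaching timestamps and geometry.
#'
#' @param path TIFF path (sidecar expected alongside).
#' @return Array `depth_px x n_angles x n_frames` of dB values with
#'   attributes `time_s` and `geometry` (a [scan_geometry()]).
#' @export
read_frames_tiff <- function(path) {
  if (!file.exists(path)) stop("read_frames_tiff: no such file: ", path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop("read_frames_tiff: missing sidecar JSON: ", sc_path)
  side <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 2) != "II")
    stop("read_frames_tiff: only little-endian TIFF is supported")
  readBin(con, integer(), 1, size = 2, endian = "little")  # 42
  ifd_off <- readBin(con, integer(), 1, size = 4, endian = "little")
  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n <- readBin(con, integer(), 1, size = 2, endian = "little")
    tags <- list()
    for (i in seq_len(n)) {
      tag <- readBin(con, integer(), 1, size = 2, endian = "little")
      type <- readBin(con, integer(), 1, size = 2, endian = "little")
      readBin(con, integer(), 1, size = 4, endian = "little")  # count
      value <- if (type == 3) {
        v <- readBin(con, integer(), 1, size = 2, endian = "little",
                     signed = FALSE)
        readBin(con, integer(), 1, size = 2, endian = "little")
        v
      } else readBin(con, integer(), 1, size = 4, endian = "little")
      tags[[as.character(tag)]] <- value
    }
    next_off <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (!identical(tags[["259"]], 1L))
      stop("read_frames_tiff: compressed TIFF not supported")
    if (!identical(tags[["258"]], 16L))
      stop("read_frames_tiff: only 16-bit samples supported")
    w <- tags[["256"]]; h <- tags[["257"]]
    seek(con, tags[["273"]])
    px <- readBin(con, integer(), w * h, size = 2, endian = "little",
                  signed = FALSE)
    pages[[length(pages) + 1]] <- t(matrix(px, nrow = w, ncol = h))
    ifd_off <- next_off
  }
  d1 <- nrow(pages[[1]]); d2 <- ncol(pages[[1]])
  out <- array(0, dim = c(d1, d2, length(pages)))
  for (f in seq_along(pages)) out[, , f] <- pages[[f]]
  out <- out * side$db_gain + side$db_offset
  attr(out, "time_s") <- side$time_s
  g <- side$geometry
  attr(out, "geometry") <- scan_geometry(
    frame_rate = g$frame_rate, n_frames = g$n_frames, depth_px = g$depth_px,
    range_mm = g$range_mm, n_angles = g$n_angles, aline_group = g$aline_group,
    sheath_od_mm = g$sheath_od_mm, pressure_rate = g$pressure_rate)
  out
}

#' Write / read a pressure trace CSV (`time_s,pressure_cmH2O`)
#'
#' @param pressure Data frame `time_s, pressure_cmH2O`.
#' @param path CSV path.
#' @return `path` / the data frame.
#' @export
write_pressure_csv <- function(pressure, path) {
  stopifnot(all(c("time_s", "pressure_cmH2O") %in% names(pressure)))
  utils::write.csv(pressure[c("time_s", "pressure_cmH2O")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_cmH2O") %in% names(df)))
    stop("read_pressure_csv: expected header time_s,pressure_cmH2O in ", path)
  df
}

#' Write a CSA series CSV (`frame,time_s,csa_mm2`)
#'
#' @param csa_series A `csa_series` or a data frame `frame,time_s,csa_mm2`.
#' @param path CSV path.
#' @export
write_csa_csv <- function(csa_series, path) {
  df <- if (inherits(csa_series, "csa_series")) csa_series$csa else csa_series
  stopifnot(all(c("frame", "time_s", "csa_mm2") %in% names(df)))
  utils::write.csv(df[c("frame", "time_s", "csa_mm2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_csa_csv
#' @export
read_csa_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "time_s", "csa_mm2") %in% names(df)))
    stop("read_csa_csv: expected header frame,time_s,csa_mm2 in ", path)
  df
}

#' Write a segmented boundary in long CSV format
#'
#' Columns `frame,column,radius_mm,aliased`, one row per frame/column.
#'
#' @param csa_series A `csa_series` from [segment_stack()].
#' @param path CSV path.
#' @export
write_boundary_csv <- function(csa_series, path) {
  stopifnot(inherits(csa_series, "csa_series"))
  b <- csa_series$boundary_mm
  df <- data.frame(frame = rep(seq_len(nrow(b)), each = ncol(b)),
                   column = rep(seq_len(ncol(b)), nrow(b)),
                   radius_mm = as.vector(t(b)),
                   aliased = as.integer(as.vector(t(csa_series$aliased))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a seed-depth CSV (`frame,column,depth_px`) into a seed matrix
#'
#' Sparse per-column surface hints standing in for the manual input of a
#' semi-automatic segmentation workflow; unlisted frame/column pairs are NA.
#'
#' @param path CSV path with header `frame,column,depth_px`.
#' @param n_frames,n_angles Dimensions of the target seed matrix.
#' @return `n_frames x n_angles` numeric matrix with NA where unseeded.
#' @export
read_seed_csv <- function(path, n_frames, n_angles) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "column", "depth_px") %in% names(df)))
    stop("read_seed_csv: expected header frame,column,depth_px in ", path)
  m <- matrix(NA_real_, n_frames, n_angles)
  keep <- df$frame >= 1 & df$frame <= n_frames &
    df$column >= 1 & df$column <= n_angles
  m[cbind(df$frame[keep], df$column[keep])] <- df$depth_px[keep]
  m
}

#' Write ground-truth artifacts of a synthetic scan
#'
#' CSV `frame,csa_mm2_true` plus a JSON with the true nCsC and tube
#' parameters.
#'
#' @param gt An `aoct_ground_truth`.
#' @param csv_path,json_path Output paths.
#' @export
write_ground_truth <- function(gt, csv_path, json_path) {
  stopifnot(inherits(gt, "aoct_ground_truth"))
  utils::write.csv(data.frame(frame = seq_along(gt$csa_mm2),
                              csa_mm2_true = gt$csa_mm2),
                   csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(ncsc_true = gt$ncsc_true,
                            tube = unclass(gt$tube),
                            catheter_offset_mm = gt$catheter_offset_mm),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
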