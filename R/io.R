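#' Read a timelapse movie from TIFF or HDF5
#'
#' TIFF: multi-page grayscale, one page per frame (2D movies) or pages in
#' `(t, z)` order with `z` fastest for volumetric movies (pass `n_z`). HDF5:
#' one dataset `"frames"` of dimension `T x H x W` (or `T x Z x H x W`) with
#' scalar attributes `bit_depth`, `frame_interval`, `pixel_size`, `source_id`.
#' Pixel values are returned unmodified.
#'
#' @param path file path.
#' @param format `"tiff"` or `"hdf5"`; inferred from the extension by default.
#' @param n_z number of z planes per time point (volumetric TIFF only).
#' @param frame_interval,pixel_size metadata defaults used when the file
#'   carries none (TIFF).
#' @return A [timelapse()] or [volumetric_timelapse()].
#' @export
read_timelapse <- function(path, format = c("auto", "tiff", "hdf5"),
                           n_z = NULL, frame_interval = 1, pixel_size = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "tiff"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
      stop("multi-channel TIFF: select a single channel before reading")
    bits <- if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L
    stack <- aperm(simplify2array(pages), c(3, 1, 2))
    if (is.null(n_z))
      return(timelapse(stack, bits, frame_interval, pixel_size, basename(path)))
    if (dim(stack)[1] %% n_z != 0) stop("page count not divisible by n_z")
    tt <- dim(stack)[1] %/% n_z
    vol <- array(0, c(tt, n_z, dim(stack)[2], dim(stack)[3]))
    for (t in seq_len(tt)) vol[t, , , ] <- stack[(t - 1) * n_z + seq_len(n_z), , ]
    return(volumetric_timelapse(vol, bits, frame_interval, pixel_size,
                                source_id = basename(path)))
  }
  frames <- rhdf5::h5read(path, "frames")
  att <- rhdf5::h5readAttributes(path, "frames")
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) stop("dataset 'frames' must be 3D or 4D")
  bd <- as.integer(att$bit_depth %||% 8L)
  fi <- as.numeric(att$frame_interval %||% frame_interval)
  ps <- att$pixel_size
  ps <- if (is.null(ps) || all(is.na(ps))) pixel_size else as.numeric(ps)
  sid <- as.character(att$source_id %||% basename(path))
  if (nd == 3L) timelapse(frames, bd, fi, ps, sid)
  else volumetric_timelapse(frames, bd, fi, ps,
                            z_spacing = if (is.null(att$z_spacing)) NULL
                                        else as.numeric(att$z_spacing),
                            source_id = sid)
}

#' Write a timelapse movie to TIFF or HDF5
#'
#' Inverse of [read_timelapse()]; round-trips are bit-exact.
#'
#' @param movie a [timelapse()] or [volumetric_timelapse()].
#' @param path output path.
#' @param format `"tiff"`, `"hdf5"` or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(movie, path, format = c("auto", "tiff", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "tiff"
  volum <- inherits(movie, "volumetric_timelapse")
  if (format == "tiff") {
    maxv <- 2^movie$bit_depth - 1
    d <- dim(movie$frames)
    pages <- if (!volum) {
      lapply(seq_len(d[1]), function(t) movie$frames[t, , ] / maxv)
    } else {
      unlist(lapply(seq_len(d[1]), function(t)
        lapply(seq_len(d[2]), function(z) movie$frames[t, z, , ] / maxv)),
        recursive = FALSE)
    }
    tiff::writeTIFF(pages, path, bits.per.sample = movie$bit_depth)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(movie$frames, path, "frames")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "frames")
    rhdf5::h5writeAttribute(movie$bit_depth, did, "bit_depth")
    rhdf5::h5writeAttribute(movie$frame_interval, did, "frame_interval")
    rhdf5::h5writeAttribute(movie$pixel_size %||% NA_real_, did, "pixel_size")
    rhdf5::h5writeAttribute(movie$source_id, did, "source_id")
    if (volum)
      rhdf5::h5writeAttribute(movie$z_spacing %||% NA_real_, did, "z_spacing")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# CSV interfaces. All on-disk and in-memory coordinates are 0-based:
# x = column, y = row, t = frame; boxes are half-open [x_min, x_max) x
# [y_min, y_max).

#' Read point annotations of apoptotic events
#'
#' CSV with header and columns `x,y,t` and optionally `label` (1 apoptotic,
#' 0 nonapoptotic; default 1) and `track_id`. Coordinates are 0-based pixel
#' column (`x`), row (`y`) and frame (`t`).
#'
#' @param path CSV path.
#' @param movie optional [timelapse()]; if given, coordinates are validated
#'   against its bounds.
#' @return A data frame with columns `x, y, t, label, track_id`.
#' @export
read_annotations <- function(path, movie = NULL) {
  df <- read.csv(path)
  req <- c("x", "y", "t")
  if (!all(req %in% names(df))) stop("annotation CSV must have columns x,y,t")
  if (is.null(df$label)) df$label <- 1L
  if (is.null(df$track_id)) df$track_id <- NA_integer_
  ann <- df[, c("x", "y", "t", "label", "track_id")]
  if (!all(ann$label %in% c(0L, 1L))) stop("label must be 0 or 1")
  if (!is.null(movie)) validate_annotations(ann, movie)
  ann
}

#' Validate annotations against a movie's bounds
#' @param annotations data frame with `x, y, t`.
#' @param movie a [timelapse()].
#' @return The annotations, invisibly; errors on out-of-bounds rows.
#' @export
validate_annotations <- function(annotations, movie) {
  d <- dim(movie$frames)
  bad <- annotations$x < 0 | annotations$x >= d[3] |
    annotations$y < 0 | annotations$y >= d[2] |
    annotations$t < 0 | annotations$t >= d[1]
  if (any(bad))
    stop(sum(bad), " annotation(s) outside movie bounds (first at row ",
         which(bad)[1], ")")
  invisible(annotations)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations[, c("x", "y", "t", "label", "track_id")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read/write detections
#'
#' CSV columns `t,x_min,y_min,x_max,y_max,prob` (0-based, half-open boxes).
#' @param path CSV path.
#' @return Data frame of detections.
#' @export
read_detections <- function(path) {
  df <- read.csv(path)
  req <- c("t", "x_min", "y_min", "x_max", "y_max", "prob")
  if (!all(req %in% names(df))) stop("detection CSV missing columns")
  df[, req]
}

#' @rdname read_detections
#' @param detections data frame with detection columns.
#' @export
write_detections <- function(detections, path) {
  write.csv(detections[, c("t", "x_min", "y_min", "x_max", "y_max", "prob")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read/write tracks
#'
#' CSV columns `track_id,t,x,y,prob` (0-based).
#' @param path CSV path.
#' @return Data frame of track points.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path)
  req <- c("track_id", "t", "x", "y", "prob")
  if (!all(req %in% names(df))) stop("track CSV missing columns")
  df[, req]
}

#' @rdname read_tracks
#' @param tracks data frame with track columns.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks[, c("track_id", "t", "x", "y", "prob")], path,
            row.names = FALSE)
  invisible(path)
}
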