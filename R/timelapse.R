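#' Timelapse container
#'
#' A single-channel timelapse movie: an integer-valued intensity array of
#' dimension `T x H x W` plus acquisition metadata. Frame `t` (0-based in all
#' user-facing coordinates of this package) is `frames[t + 1, , ]`, a matrix
#' whose rows are image rows (`y`) and whose columns are image columns (`x`).
#'
#' @param frames numeric array, dim `c(T, H, W)`, non-negative integers.
#' @param bit_depth 8 or 16.
#' @param frame_interval minutes per frame (> 0).
#' @param pixel_size micrometers per pixel, or `NULL` if unknown.
#' @param source_id free-text movie identifier.
#' @return An object of class `timelapse`.
#' @export
timelapse <- function(frames, bit_depth = 8L, frame_interval = 1,
                      pixel_size = NULL, source_id = "") {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[1] >= 1L)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  maxv <- 2^bit_depth - 1
  if (min(frames) < 0 || max(frames) > maxv)
    stop("intensities outside [0, 2^bit_depth - 1]")
  structure(list(frames = frames, bit_depth = as.integer(bit_depth),
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 source_id = source_id),
            class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("timelapse: %d frames, %d x %d px, %d-bit, %.3g min/frame%s\n",
              d[1], d[2], d[3], x$bit_depth, x$frame_interval,
              if (is.null(x$pixel_size)) "" else
                sprintf(", %.3g um/px", x$pixel_size)))
  invisible(x)
}

#' @export
dim.timelapse <- function(x) dim(x$frames)

#' Volumetric timelapse container
#'
#' A volumetric movie: `T x Z x H x W` intensity array. Frame `t`, plane `z`
#' is `frames[t + 1, z + 1, , ]`.
#'
#' @param frames numeric array, dim `c(T, Z, H, W)` with `Z >= 2`.
#' @param z_spacing micrometers between planes, or `NULL`.
#' @inheritParams timelapse
#' @return An object of class `volumetric_timelapse`.
#' @export
volumetric_timelapse <- function(frames, bit_depth = 8L, frame_interval = 1,
                                 pixel_size = NULL, z_spacing = NULL,
                                 source_id = "") {
  stopifnot(length(dim(frames)) == 4L, dim(frames)[1] >= 1L,
            dim(frames)[2] >= 2L)
  obj <- timelapse(array(0, c(1, 1, 1)), bit_depth, frame_interval,
                   pixel_size, source_id)
  obj$frames <- frames
  obj$z_spacing <- z_spacing
  class(obj) <- c("volumetric_timelapse", "timelapse")
  obj
}

#' Maximum intensity projection
#'
#' Flattens a volumetric timelapse by the per-frame, per-pixel maximum over z,
#' the standard projection used to feed volumetric acquisitions to the 2D
#' detection pipeline.
#'
#' @param volume a [volumetric_timelapse()].
#' @return A [timelapse()] with the same `T`, `H`, `W` and metadata.
#' @export
max_project <- function(volume) {
  stopifnot(inherits(volume, "volumetric_timelapse"))
  d <- dim(volume$frames)
  planes <- lapply(seq_len(d[2]), function(z) volume$frames[, z, , , drop = FALSE])
  out <- do.call(pmax, planes)
  dim(out) <- d[c(1, 3, 4)]
  timelapse(out, volume$bit_depth, volume$frame_interval, volume$pixel_size,
            volume$source_id)
}

#' Quantile-based 8-bit normalization
#'
#' Linearly rescales a movie so that the `q_low` quantile of the whole-movie
#' intensity distribution maps to 0 and the `q_high` quantile to 255, clips to
#' \[0, 255\] and floors, producing an 8-bit movie. This is the standardization
#' applied to 16-bit acquisitions before region proposal and classification.
#'
#' Quantiles are computed by linear interpolation over the sorted whole-movie
#' sample. A constant movie (equal quantiles) normalizes to all zeros with a
#' warning rather than erroring, so batch processing never aborts.
#'
#' @param movie a [timelapse()].
#' @param q_low,q_high quantile probabilities, `q_low < q_high`.
#' @return An 8-bit [timelapse()].
#' @export
normalize_to_uint8 <- function(movie, q_low = 0.001, q_high = 0.999) {
  stopifnot(inherits(movie, "timelapse"), q_low < q_high)
  qs <- quantile(movie$frames, c(q_low, q_high), names = FALSE, type = 7)
  out <- movie
  out$bit_depth <- 8L
  if (qs[1] == qs[2]) {
    warning("constant movie: normalizing to all zeros")
    out$frames <- array(0, dim(movie$frames))
    return(out)
  }
  scaled <- (movie$frames - qs[1]) / (qs[2] - qs[1]) * 255
  out$frames <- floor(clamp(scaled, 0, 255))
  out
}
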