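# Multi-object centroid tracking of per-frame detections.

#' Link detections into apoptotic-event tracks
#'
#' Frame-by-frame greedy nearest-neighbour assignment by centroid Euclidean
#' distance: candidate (track, detection) pairs are processed in increasing
#' distance (ties broken by lower track id, then detection order), an
#' assignment is allowed only within `dist_threshold` pixels, unmatched
#' detections open new tracks, a track that has not been updated for more
#' than `gap` frames is closed, and tracks with fewer than two detections are
#' discarded. A track's centroid for matching is the box centre of its most
#' recent detection.
#'
#' @param detections data frame `t, x_min, y_min, x_max, y_max, prob` (or
#'   `t, x, y, prob`).
#' @param gap maximum number of consecutive missing frames before a track is
#'   closed (default 3).
#' @param dist_threshold maximum linking distance in pixels (default 10).
#' @return Data frame `track_id, t, x, y, prob` sorted by track then frame.
#' @export
track_detections <- function(detections, gap = 3L, dist_threshold = 10) {
  if (!nrow(detections))
    return(data.frame(track_id = integer(0), t = integer(0), x = numeric(0),
                      y = numeric(0), prob = numeric(0)))
  if (is.null(detections$x)) {
    detections$x <- (detections$x_min + detections$x_max) / 2
    detections$y <- (detections$y_min + detections$y_max) / 2
  }
  detections <- detections[order(detections$t), , drop = FALSE]
  tracks <- list()   # each: list(id, last_t, x, y, rows = data frame)
  next_id <- 1L
  for (t0 in sort(unique(detections$t))) {
    live <- which(vapply(tracks, function(tr) t0 - tr$last_t <= gap + 1L,
                         logical(1)))
    dets <- detections[detections$t == t0, , drop = FALSE]
    nd <- nrow(dets)
    assigned_det <- rep(FALSE, nd)
    if (length(live) && nd) {
      pairs <- expand.grid(tr = live, de = seq_len(nd))
      pairs$dist <- sqrt(
        (vapply(tracks[pairs$tr], `[[`, numeric(1), "x") - dets$x[pairs$de])^2 +
        (vapply(tracks[pairs$tr], `[[`, numeric(1), "y") - dets$y[pairs$de])^2)
      pairs <- pairs[pairs$dist <= dist_threshold, , drop = FALSE]
      pairs <- pairs[order(pairs$dist,
                           vapply(tracks[pairs$tr], `[[`, integer(1), "id"),
                           pairs$de), , drop = FALSE]
      used_tr <- logical(length(tracks))
      for (r in seq_len(nrow(pairs))) {
        ti <- pairs$tr[r]; di <- pairs$de[r]
        if (used_tr[ti] || assigned_det[di]) next
        used_tr[ti] <- TRUE
        assigned_det[di] <- TRUE
        tracks[[ti]]$last_t <- t0
        tracks[[ti]]$x <- dets$x[di]
        tracks[[ti]]$y <- dets$y[di]
        tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows,
                                   data.frame(t = t0, x = dets$x[di],
                                              y = dets$y[di],
                                              prob = dets$prob[di]))
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, last_t = t0, x = dets$x[di], y = dets$y[di],
        rows = data.frame(t = t0, x = dets$x[di], y = dets$y[di],
                          prob = dets$prob[di]))
      next_id <- next_id + 1L
    }
  }
  keep <- Filter(function(tr) nrow(tr$rows) >= 2L, tracks)
  if (!length(keep))
    return(data.frame(track_id = integer(0), t = integer(0), x = numeric(0),
                      y = numeric(0), prob = numeric(0)))
  out <- do.call(rbind, lapply(keep, function(tr)
    cbind(track_id = tr$id, tr$rows)))
  out <- out[order(out$track_id, out$t), ]
  rownames(out) <- NULL
  out
}

#' Summarize tracks as point events
#'
#' A track's event time is its first frame and its event location the median
#' of its centroids (robust to per-frame jitter).
#'
#' @param tracks data frame `track_id, t, x, y[, prob]`.
#' @return Data frame `track_id, x, y, t[, prob]` (one row per track).
#' @export
tracks_to_events <- function(tracks) {
  if (!nrow(tracks))
    return(data.frame(track_id = integer(0), x = numeric(0), y = numeric(0),
                      t = integer(0)))
  out <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr)
    data.frame(track_id = tr$track_id[1], x = median(tr$x), y = median(tr$y),
               t = min(tr$t),
               prob = if (is.null(tr$prob)) NA_real_ else max(tr$prob))))
  rownames(out) <- NULL
  out
}

#' Track kinematics
#'
#' Instantaneous speed (centroid displacement per unit time; micrometers per
#' minute when `pixel_size` is known, else pixels per frame) and, when a
#' reference point is given, the Euclidean distance to it per frame — the
#' measurements used to characterize bystander-cell responses around an
#' apoptotic centroid.
#'
#' @param track data frame `t, x, y` for one trajectory (frames strictly
#'   increasing).
#' @param frame_interval minutes per frame.
#' @param pixel_size micrometers per pixel, or `NULL` for pixel units.
#' @param reference_point optional `c(x, y)`.
#' @return List with `speed` (data frame `t, speed`, one row per step,
#'   timed at the later frame) and `distance` (data frame `t, dist`, or
#'   `NULL` without a reference point).
#' @export
track_kinematics <- function(track, frame_interval = 1, pixel_size = NULL,
                             reference_point = NULL) {
  track <- track[order(track$t), , drop = FALSE]
  if (nrow(track) < 2L) stop("speed requires a track of length >= 2")
  scale <- if (is.null(pixel_size)) 1 else pixel_size
  dt <- diff(track$t) * (if (is.null(pixel_size)) 1 else frame_interval)
  step <- sqrt(diff(track$x)^2 + diff(track$y)^2) * scale
  speed <- data.frame(t = track$t[-1], speed = step / dt)
  dist <- NULL
  if (!is.null(reference_point))
    dist <- data.frame(t = track$t,
                       dist = sqrt((track$x - reference_point[1])^2 +
                                     (track$y - reference_point[2])^2) * scale)
  list(speed = speed, distance = dist)
}
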