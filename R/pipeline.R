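# Full-movie inference: windowing around each proposal, classification,
# probability thresholding, non-maximum suppression, heatmaps and counts.

#' Detection pipeline configuration
#'
#' Defaults follow the published deployment parameters: a 9-frame temporal
#' window (the expected duration of an apoptotic event) subsampled to the
#' classifier's 5 input frames, a probability threshold of 0.995 (in vitro;
#' use 0.95 in vivo), non-maximum suppression at 0.1 overlap, and the
#' size/brightness proposal filters of [proposal_config()].
#'
#' @param window_frames temporal window length in frames.
#' @param clip_len classifier input length K.
#' @param prob_threshold minimum P(apoptotic) for a detection.
#' @param nms_overlap IoU above which a lower-probability box is suppressed.
#' @param proposal a [proposal_config()].
#' @param gap,dist_threshold tracker parameters (see [track_detections()]).
#' @param batch_size classification batch size.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_frames = 9L, clip_len = 5L,
                            prob_threshold = 0.995, nms_overlap = 0.1,
                            proposal = proposal_config(), gap = 3L,
                            dist_threshold = 10, batch_size = 256L) {
  stopifnot(prob_threshold > 0, prob_threshold < 1, window_frames >= 1L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Frame indices of the temporal classification window
#'
#' The window `[t - floor(w/2), t + floor(w/2)]` centred on `t` is clamped
#' to `[0, T - 1]` by edge replication and then uniformly subsampled to `k`
#' indices (first and last included), so events at the movie boundaries stay
#' detectable.
#'
#' @param t 0-based centre frame.
#' @param window window length in frames.
#' @param k number of indices to return.
#' @param T movie length in frames.
#' @return Integer vector of `k` 0-based frame indices.
#' @export
window_indices <- function(t, window = 9L, k = 5L, T) {
  stopifnot(t >= 0, t < T)
  half <- window %/% 2L
  win <- clamp(seq.int(t - half, t + half), 0L, T - 1L)
  win[uniform_indices(length(win), k)]
}

box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a[3], b[, 3]) - pmax(a[1], b[, 1]))
  iy <- pmax(0, pmin(a[4], b[, 4]) - pmax(a[2], b[, 2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (area_a + area_b - inter)
}

#' Non-maximum suppression
#'
#' Greedy: boxes are visited in decreasing probability (ties broken by input
#' order); each kept box suppresses all remaining boxes whose IoU with it
#' exceeds `overlap_threshold`.
#'
#' @param detections data frame with `x_min, y_min, x_max, y_max, prob`
#'   (one frame's detections).
#' @param overlap_threshold IoU threshold (default 0.1).
#' @return The kept subset, ordered by decreasing probability.
#' @export
nms <- function(detections, overlap_threshold = 0.1) {
  if (nrow(detections) <= 1L) return(detections)
  ord <- order(-detections$prob, seq_len(nrow(detections)))
  d <- detections[ord, , drop = FALSE]
  m <- as.matrix(d[, c("x_min", "y_min", "x_max", "y_max")])
  keep <- logical(nrow(d))
  avail <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!avail[i]) next
    keep[i] <- TRUE
    rest <- which(avail & seq_len(nrow(d)) > i)
    if (length(rest)) {
      iou <- box_iou(m[i, ], m[rest, , drop = FALSE])
      avail[rest[iou > overlap_threshold]] <- FALSE
    }
  }
  d[keep, , drop = FALSE]
}

#' Detect apoptotic events in a movie
#'
#' For every frame: propose candidate boxes, cut the 59x59 clip at the
#' temporal window indices around the frame, classify the clip sequences in
#' batches, keep boxes with P(apoptotic) at or above the threshold, and apply
#' per-frame non-maximum suppression. The classification clip is always the
#' fixed 59x59 window centred on the box centroid (boxes are constrained to
#' 20-40 px, so the clip contains them).
#'
#' @param movie an 8-bit [timelapse()].
#' @param model a trained `conv_transformer`.
#' @param cfg a [pipeline_config()].
#' @return Data frame `t, x_min, y_min, x_max, y_max, prob`, per-frame
#'   detections sorted by decreasing probability within each frame.
#' @export
detect_events <- function(movie, model, cfg = pipeline_config()) {
  stopifnot(inherits(movie, "timelapse"), movie$bit_depth == 8L)
  d <- dim(movie$frames)
  TT <- d[1]
  K <- cfg$clip_len
  cand <- vector("list", TT)
  for (t0 in 0:(TT - 1L)) {
    b <- propose_rois(movie$frames[t0 + 1L, , ], cfg$proposal)
    if (nrow(b)) {
      b$t <- t0
      cand[[t0 + 1L]] <- b
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand))
    return(data.frame(t = integer(0), x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0),
                      prob = numeric(0)))
  n <- nrow(cand)
  probs <- numeric(n)
  S <- model$cfg$input_size
  for (start in seq(1L, n, by = cfg$batch_size)) {
    idx <- start:min(start + cfg$batch_size - 1L, n)
    X <- array(0, c(length(idx), K, S, S))
    for (j in seq_along(idx)) {
      i <- idx[j]
      ts <- window_indices(cand$t[i], cfg$window_frames, K, TT)
      X[j, , , ] <- extract_clip(movie, (cand$x_min[i] + cand$x_max[i]) / 2,
                                 (cand$y_min[i] + cand$y_max[i]) / 2, ts,
                                 size = S)
    }
    probs[idx] <- ct_predict(model, X)
  }
  cand$prob <- probs
  det <- cand[cand$prob >= cfg$prob_threshold, , drop = FALSE]
  if (!nrow(det))
    return(det[, c("t", "x_min", "y_min", "x_max", "y_max", "prob")])
  out <- do.call(rbind, lapply(split(det, det$t), nms,
                               overlap_threshold = cfg$nms_overlap))
  rownames(out) <- NULL
  out[, c("t", "x_min", "y_min", "x_max", "y_max", "prob")]
}

#' Probability heatmap of detected events
#'
#' Each detection splats its probability over its box with a Gaussian weight
#' centred on the box centre (sigma = edge/4); the map aggregates detections
#' by per-pixel maximum (over time for the 2D map, within each frame for the
#' per-frame stack) and is clipped to \[0, 1\].
#'
#' @param detections detection data frame (see [detect_events()]).
#' @param dims movie dimensions `c(T, H, W)` (or a [timelapse()]).
#' @param per_frame return a `T x H x W` stack instead of a 2D map.
#' @return `H x W` matrix in \[0, 1\], or a `T x H x W` array.
#' @export
probability_heatmap <- function(detections, dims, per_frame = FALSE) {
  if (inherits(dims, "timelapse")) dims <- dim(dims$frames)
  H <- dims[2]; W <- dims[3]; TT <- dims[1]
  splat <- function(map, det) {
    for (i in seq_len(nrow(det))) {
      cx <- (det$x_min[i] + det$x_max[i]) / 2
      cy <- (det$y_min[i] + det$y_max[i]) / 2
      sg <- (det$x_max[i] - det$x_min[i]) / 4
      xs <- (det$x_min[i] + 1L):det$x_max[i]
      ys <- (det$y_min[i] + 1L):det$y_max[i]
      g <- det$prob[i] *
        exp(-0.5 * (outer((ys - 1 - cy)^2, (xs - 1 - cx)^2, `+`)) / sg^2)
      map[ys, xs] <- pmax(map[ys, xs], g)
    }
    map
  }
  if (!per_frame) return(clamp(splat(matrix(0, H, W), detections), 0, 1))
  out <- array(0, c(TT, H, W))
  for (t0 in unique(detections$t))
    out[t0 + 1L, , ] <- clamp(
      splat(matrix(0, H, W), detections[detections$t == t0, , drop = FALSE]),
      0, 1)
  out
}

#' Cumulative event counts per frame
#'
#' Counts events by their first frame; the series is nondecreasing and its
#' final value equals the number of events.
#'
#' @param event_t integer vector of 0-based event frames (one per event;
#'   for tracks, the track's first frame).
#' @param T movie length in frames.
#' @return Data frame `t, count` for `t` in `0:(T-1)`.
#' @export
cumulative_counts <- function(event_t, T) {
  counts <- cumsum(tabulate(event_t + 1L, nbins = T))
  data.frame(t = 0:(T - 1L), count = counts)
}
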