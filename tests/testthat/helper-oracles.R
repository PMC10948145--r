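# Brute-force reference implementations used to validate the package's
# optimized code paths, plus small data helpers.

# O(n^2) NMS oracle: literal restatement of the greedy rule.
oracle_nms <- function(det, thr) {
  ord <- order(-det$prob, seq_len(nrow(det)))
  d <- det[ord, , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (k in kept) {
      iou <- oracle_iou(as.numeric(d[i, c("x_min", "y_min", "x_max", "y_max")]),
                        as.numeric(k[c("x_min", "y_min", "x_max", "y_max")]))
      if (iou > thr) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- d[i, ]
  }
  do.call(rbind, kept)
}

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Random detection frame for NMS tests.
random_boxes <- function(n, size = 200L) {
  x <- runif(n, 0, size - 41)
  y <- runif(n, 0, size - 41)
  e <- sample(20:40, n, replace = TRUE)
  data.frame(x_min = floor(x), y_min = floor(y), x_max = floor(x) + e,
             y_max = floor(y) + e, prob = runif(n))
}

# Sort-based quantile + linear map oracle for normalize_to_uint8.
oracle_normalize <- function(values, q_low, q_high) {
  qs <- quantile(values, c(q_low, q_high), names = FALSE, type = 7)
  if (qs[1] == qs[2]) return(rep(0, length(values)))
  floor(pmin(pmax((values - qs[1]) / (qs[2] - qs[1]) * 255, 0), 255))
}

# Small deterministic movie helper.
toy_movie <- function(T = 4L, H = 16L, W = 12L, bit_depth = 8L, seed = 1L) {
  maxv <- 2^bit_depth - 1
  fr <- apodetect:::with_seed(seed,
    array(sample(0:maxv, T * H * W, replace = TRUE), c(T, H, W)))
  timelapse(fr, bit_depth = bit_depth, frame_interval = 2, pixel_size = 0.6,
            source_id = "toy")
}
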