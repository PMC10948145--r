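# Region proposal: candidate boxes that may contain apoptotic cells.
# Boxes are 0-based half-open [x_min, x_max) x [y_min, y_max).

#' Proposal configuration
#'
#' Two interchangeable proposers are provided. `"selective"` is a selective-
#' search style procedure: a graph-based over-segmentation (Felzenszwalb-
#' Huttenlocher on the 4-connected intensity graph) followed by iterative
#' merging of adjacent regions by intensity- and size-similarity, emitting a
#' box per region ever formed. `"blob"` is a deterministic threshold +
#' connected-components proposer that dilates each blob to a box within the
#' size bounds; it is cheaper and is the default for full-movie runs.
#' Both feed the same size/brightness filter: both box edges within
#' `[min_edge, max_edge]` pixels inclusive and mean intensity `>=`
#' `min_brightness` (exclusion is "below 40", so the boundary is kept).
#'
#' @param method `"blob"` or `"selective"`.
#' @param min_edge,max_edge box edge bounds in pixels.
#' @param min_brightness minimum mean 8-bit intensity inside the box.
#' @param threshold blob proposer: `"otsu"` or a fixed 8-bit threshold.
#' @param felz_k,felz_min_size granularity of the over-segmentation.
#' @param sim_floor stop merging when the best pair similarity (range 0-2)
#'   falls below this.
#' @return A list of class `proposal_config`.
#' @export
proposal_config <- function(method = c("blob", "selective"),
                            min_edge = 20L, max_edge = 40L,
                            min_brightness = 40,
                            threshold = "otsu",
                            felz_k = 300, felz_min_size = 10L,
                            sim_floor = 1.2) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "proposal_config")
}

box_mean_intensity <- function(frame, x_min, y_min, x_max, y_max) {
  vapply(seq_along(x_min), function(i)
    mean(frame[(y_min[i] + 1L):y_max[i], (x_min[i] + 1L):x_max[i]]),
    numeric(1))
}

#' Filter candidate boxes by size and brightness
#'
#' Keeps boxes whose edges are both within `[min_edge, max_edge]` pixels
#' (inclusive) and whose mean 8-bit intensity is at least `min_brightness`;
#' order is preserved.
#'
#' @param boxes data frame with `x_min, y_min, x_max, y_max` (0-based,
#'   half-open).
#' @param frame the 8-bit image matrix the boxes refer to.
#' @param min_edge,max_edge,min_brightness filter parameters.
#' @return The surviving subset, with a `mean_intensity` column.
#' @export
filter_boxes <- function(boxes, frame, min_edge = 20L, max_edge = 40L,
                         min_brightness = 40) {
  if (!nrow(boxes)) {
    boxes$mean_intensity <- numeric(0)
    return(boxes)
  }
  ex <- boxes$x_max - boxes$x_min
  ey <- boxes$y_max - boxes$y_min
  boxes$mean_intensity <- box_mean_intensity(frame, boxes$x_min, boxes$y_min,
                                             boxes$x_max, boxes$y_max)
  keep <- ex >= min_edge & ex <= max_edge & ey >= min_edge & ey <= max_edge &
    boxes$mean_intensity >= min_brightness
  boxes[keep, , drop = FALSE]
}

# Centre a box of the given edge on (cx, cy), shifted to stay inside the
# frame. Returns c(x_min, y_min, x_max, y_max), half-open.
centered_box <- function(cx, cy, edge, H, W) {
  x_min <- clamp(round(cx) - edge %/% 2L, 0L, W - edge)
  y_min <- clamp(round(cy) - edge %/% 2L, 0L, H - edge)
  c(x_min, y_min, x_min + edge, y_min + edge)
}

blob_propose <- function(frame, cfg) {
  H <- nrow(frame); W <- ncol(frame)
  thr <- if (identical(cfg$threshold, "otsu"))
    EBImage::otsu(EBImage::Image(t(frame) / 255), range = c(0, 1)) * 255
  else cfg$threshold
  maskm <- frame > thr
  lab <- EBImage::bwlabel(EBImage::Image(t(maskm)))
  labm <- t(EBImage::imageData(lab))   # back to row = y
  nlab <- max(labm)
  if (nlab == 0) return(empty_boxes())
  area <- tabulate(labm[labm > 0], nlab)
  # seed one box per intensity local maximum inside the mask, so touching
  # cells in one connected component each get their own box; plateaus (e.g.
  # saturated cores) are collapsed to their centroid
  dil <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(frame) / 255), EBImage::makeBrush(5, "box")))) * 255
  seedm <- maskm & (frame >= dil - 1e-9)
  if (!any(seedm)) return(empty_boxes())
  slab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(seedm)))))
  ns <- max(slab)
  sidx <- which(slab > 0, arr.ind = TRUE)
  sv <- slab[slab > 0]
  scount <- tabulate(sv, ns)
  cy <- (as.numeric(rowsum(as.numeric(sidx[, 1]), sv)) / scount) - 1
  cx <- (as.numeric(rowsum(as.numeric(sidx[, 2]), sv)) / scount) - 1
  # component each seed belongs to, and how many seeds share it: the edge is
  # sized from the component area split among its seeds (one cell's share)
  comp <- labm[cbind(round(cy) + 1L, round(cx) + 1L)]
  comp[comp == 0L] <- labm[cbind(sidx[match(seq_len(ns), sv), 1],
                                 sidx[match(seq_len(ns), sv), 2])][comp == 0L]
  seeds_in_comp <- tabulate(comp, nlab)
  keep <- which(area[comp] >= 4)
  if (!length(keep)) return(empty_boxes())
  out <- t(vapply(keep, function(i) {
    a <- area[comp[i]] / max(1L, seeds_in_comp[comp[i]])
    edge <- as.integer(clamp(2L * round(1.3 * sqrt(a / pi)) + 15L,
                             cfg$min_edge, cfg$max_edge))
    centered_box(cx[i], cy[i], edge, H, W)
  }, numeric(4)))
  data.frame(x_min = out[, 1], y_min = out[, 2], x_max = out[, 3],
             y_max = out[, 4])
}

empty_boxes <- function() {
  data.frame(x_min = integer(0), y_min = integer(0), x_max = integer(0),
             y_max = integer(0))
}

selective_propose <- function(frame, cfg) {
  H <- nrow(frame); W <- ncol(frame)
  lab <- .felz_segment(frame, cfg$felz_k, cfg$felz_min_size)
  n <- max(lab)
  size <- tabulate(lab, n)
  tot <- rowsum(as.numeric(frame), as.vector(lab))[, 1]
  mu <- tot / size
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- as.vector(lab)
  x0 <- as.numeric(tapply(idx[, 2], lv, min)) - 1
  x1 <- as.numeric(tapply(idx[, 2], lv, max))
  y0 <- as.numeric(tapply(idx[, 1], lv, min)) - 1
  y1 <- as.numeric(tapply(idx[, 1], lv, max))
  # adjacency from 4-neighbour label changes
  pr <- rbind(cbind(as.vector(lab[-H, ]), as.vector(lab[-1, ])),
              cbind(as.vector(lab[, -W]), as.vector(lab[, -1])))
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  pr <- unique(t(apply(pr, 1, sort)))
  adj <- vector("list", 2L * n)
  for (i in seq_len(nrow(pr))) {
    adj[[pr[i, 1]]] <- c(adj[[pr[i, 1]]], pr[i, 2])
    adj[[pr[i, 2]]] <- c(adj[[pr[i, 2]]], pr[i, 1])
  }
  alive <- c(rep(TRUE, n), rep(FALSE, n))
  boxes <- data.frame(x_min = x0, y_min = y0, x_max = x1, y_max = y1)
  simil <- function(a, b)
    (1 - abs(mu[a] - mu[b]) / 255) + (1 - (size[a] + size[b]) / (H * W))
  repeat {
    live <- which(alive[seq_along(adj)])
    best <- c(NA, NA); best_s <- -Inf
    for (a in live) for (b in adj[[a]]) if (b > a && alive[b]) {
      s <- simil(a, b)
      if (s > best_s) { best_s <- s; best <- c(a, b) }
    }
    if (!is.finite(best_s) || best_s < cfg$sim_floor) break
    a <- best[1]; b <- best[2]
    new <- length(size) + 1L
    size[new] <- size[a] + size[b]
    mu[new] <- (mu[a] * size[a] + mu[b] * size[b]) / size[new]
    x0[new] <- min(x0[a], x0[b]); x1[new] <- max(x1[a], x1[b])
    y0[new] <- min(y0[a], y0[b]); y1[new] <- max(y1[a], y1[b])
    boxes <- rbind(boxes, data.frame(x_min = x0[new], y_min = y0[new],
                                     x_max = x1[new], y_max = y1[new]))
    adj[[new]] <- setdiff(unique(c(adj[[a]], adj[[b]])), c(a, b))
    for (v in adj[[new]]) adj[[v]] <- unique(c(setdiff(adj[[v]], c(a, b)), new))
    alive[c(a, b)] <- FALSE
    alive[new] <- TRUE
    if (length(adj) < new) adj[new] <- list(adj[[new]])
  }
  unique(boxes)
}

#' Propose candidate regions in a frame
#'
#' Runs the configured proposer and applies the size/brightness filter.
#' Blank frames legally yield an empty result (nothing survives the
#' brightness filter).
#'
#' @param frame 8-bit image matrix (row = y).
#' @param cfg a [proposal_config()].
#' @return Data frame `x_min, y_min, x_max, y_max, mean_intensity`
#'   (0-based, half-open).
#' @export
propose_rois <- function(frame, cfg = proposal_config()) {
  stopifnot(is.matrix(frame))
  boxes <- switch(cfg$method,
                  blob = blob_propose(frame, cfg),
                  selective = selective_propose(frame, cfg))
  boxes <- unique(boxes)
  filter_boxes(boxes, frame, cfg$min_edge, cfg$max_edge, cfg$min_brightness)
}
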