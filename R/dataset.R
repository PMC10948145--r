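# Clip extraction and training-set assembly. A "clip set" is the package's
# labelled sequence container: a list of K_i x 59 x 59 8-bit arrays (frames
# first) with per-clip label, provenance and centre coordinates.

CLIP_SIZE <- 59L

# Reflect (symmetric, half-sample) 0-based indices into [0, n).
sym_index <- function(idx, n) {
  p <- idx %% (2L * n)
  ifelse(p >= n, 2L * n - 1L - p, p)
}

new_clip_set <- function(clips, label, movie_id, center_t, center_x, center_y) {
  structure(list(clips = clips, label = as.integer(label),
                 movie_id = movie_id, center_t = as.integer(center_t),
                 center_x = center_x, center_y = center_y),
            class = "clip_set")
}

#' @export
print.clip_set <- function(x, ...) {
  cat(sprintf("clip_set: %d clips (%d apoptotic / %d nonapoptotic)\n",
              length(x$clips), sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

#' @export
length.clip_set <- function(x) length(x$clips)

clip_set_subset <- function(cs, i) {
  new_clip_set(cs$clips[i], cs$label[i], cs$movie_id[i], cs$center_t[i],
               cs$center_x[i], cs$center_y[i])
}

clip_set_bind <- function(a, b) {
  new_clip_set(c(a$clips, b$clips), c(a$label, b$label),
               c(a$movie_id, b$movie_id), c(a$center_t, b$center_t),
               c(a$center_x, b$center_x), c(a$center_y, b$center_y))
}

#' Extract a spatiotemporal clip from a movie
#'
#' Cuts a `size x size` window centred on the 0-based pixel coordinate
#' `(x, y)` at the given 0-based frame indices. Frame indices are clamped to
#' the movie; spatial windows crossing the border are completed by symmetric
#' reflection. The source movie must be at least `size` pixels in each
#' spatial dimension.
#'
#' @param movie a [timelapse()] (8-bit).
#' @param x,y 0-based centre coordinates.
#' @param ts integer vector of 0-based frame indices.
#' @param size clip edge in pixels.
#' @return Array `length(ts) x size x size`.
#' @export
extract_clip <- function(movie, x, y, ts, size = CLIP_SIZE) {
  d <- dim(movie$frames)
  if (d[2] < size || d[3] < size)
    stop("movie smaller than the ", size, "x", size, " clip window")
  half <- (size - 1L) %/% 2L
  xs <- sym_index(seq.int(round(x) - half, length.out = size), d[3])
  ys <- sym_index(seq.int(round(y) - half, length.out = size), d[2])
  ts <- clamp(as.integer(ts), 0L, d[1] - 1L)
  out <- array(0, c(length(ts), size, size))
  for (i in seq_along(ts)) out[i, , ] <- movie$frames[ts[i] + 1L, ys + 1L, xs + 1L]
  out
}

#' Extract training crops around annotated events
#'
#' For each annotation, cuts the 59x59 window centred on `(x, y)` at
#' `n_steps` frames whose times are linearly spaced over `window_minutes`
#' relative to the annotated frame, converted to the nearest frame index and
#' clamped to the movie. The default window (-10 to +50 min in 7 steps)
#' captures the cell before the onset of apoptosis and the full morphological
#' sequence that follows.
#'
#' @param movie a [timelapse()] with a known `frame_interval`.
#' @param annotations data frame with 0-based `x, y, t` (and optional
#'   `label`).
#' @param window_minutes length-2 numeric, minutes relative to the event.
#' @param n_steps number of time steps.
#' @return A `clip_set` (labels taken from the annotations, default 1).
#' @export
extract_training_crops <- function(movie, annotations,
                                   window_minutes = c(-10, 50), n_steps = 7L) {
  validate_annotations(annotations, movie)
  offs <- round_half_up(lin_space(window_minutes[1], window_minutes[2],
                                  n_steps) / movie$frame_interval)
  clips <- lapply(seq_len(nrow(annotations)), function(i)
    extract_clip(movie, annotations$x[i], annotations$y[i],
                 annotations$t[i] + offs))
  lab <- if (is.null(annotations$label)) 1L else annotations$label
  new_clip_set(clips, rep_len(lab, nrow(annotations)),
               rep(movie$source_id, nrow(annotations)), annotations$t,
               annotations$x, annotations$y)
}

#' Frame offsets of the training-crop window
#'
#' The 0-based frame offsets (relative to the annotated frame) produced by
#' the linear minute spacing of [extract_training_crops()].
#'
#' @inheritParams extract_training_crops
#' @param frame_interval minutes per frame.
#' @return Integer vector of `n_steps` frame offsets.
#' @export
crop_frame_offsets <- function(frame_interval, window_minutes = c(-10, 50),
                               n_steps = 7L) {
  as.integer(round_half_up(lin_space(window_minutes[1], window_minutes[2],
                                     n_steps) / frame_interval))
}

#' Subsample a clip to a fixed number of frames
#'
#' Picks `k` uniformly spaced frame indices over the input (first and last
#' always included when the input has at least 2 frames); inputs shorter than
#' `k` repeat edge frames. This is the data-loader step that standardizes
#' variable-length training sequences to the classifier's fixed input length.
#'
#' @param clip array `n x H x W`.
#' @param k target frame count (default 5, the classifier input length).
#' @return Array `k x H x W`.
#' @export
sample_fixed_length <- function(clip, k = 5L) {
  idx <- uniform_indices(dim(clip)[1], k)
  clip[idx, , , drop = FALSE]
}

# Bilinear sampling of a single frame (matrix, row = y) at 0-based
# coordinates, with symmetric edge handling.
bilinear_sample <- function(frame, xq, yq) {
  H <- nrow(frame); W <- ncol(frame)
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  ix0 <- sym_index(as.integer(x0), W) + 1L
  ix1 <- sym_index(as.integer(x0) + 1L, W) + 1L
  iy0 <- sym_index(as.integer(y0), H) + 1L
  iy1 <- sym_index(as.integer(y0) + 1L, H) + 1L
  v00 <- frame[cbind(iy0, ix0)]; v01 <- frame[cbind(iy0, ix1)]
  v10 <- frame[cbind(iy1, ix0)]; v11 <- frame[cbind(iy1, ix1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Augmentation configuration for 2D clips
#'
#' One random draw of horizontal/vertical shift, zoom, rotation and flips is
#' applied identically to every frame of a clip, preserving label, spatial
#' size and frame count.
#'
#' @param shift_frac maximum shift as a fraction of the clip edge.
#' @param zoom_range length-2 multiplicative zoom range.
#' @param rotation_deg maximum rotation magnitude in degrees.
#' @param flip_h,flip_v allow horizontal / vertical flips.
#' @return A list of class `loader_config`.
#' @export
loader_config <- function(shift_frac = 0.1, zoom_range = c(0.9, 1.1),
                          rotation_deg = 20, flip_h = TRUE, flip_v = TRUE) {
  structure(list(shift_frac = shift_frac, zoom_range = zoom_range,
                 rotation_deg = rotation_deg, flip_h = flip_h,
                 flip_v = flip_v), class = "loader_config")
}

#' Randomly augment a clip
#'
#' @param clip array `K x H x W` (8-bit values).
#' @param cfg a [loader_config()].
#' @param seed RNG seed for the single transform draw.
#' @return The augmented clip, same dimensions.
#' @export
augment2d <- function(clip, cfg = loader_config(), seed = 1L) {
  d <- dim(clip)
  draw <- with_seed(seed, list(
    sx = runif(1, -1, 1) * cfg$shift_frac * d[3],
    sy = runif(1, -1, 1) * cfg$shift_frac * d[2],
    zoom = runif(1, cfg$zoom_range[1], cfg$zoom_range[2]),
    rot = runif(1, -1, 1) * cfg$rotation_deg * pi / 180,
    fh = cfg$flip_h && runif(1) < 0.5,
    fv = cfg$flip_v && runif(1) < 0.5))
  apply_affine_clip(clip, draw)
}

apply_affine_clip <- function(clip, draw) {
  d <- dim(clip)
  cx <- (d[3] - 1) / 2; cy <- (d[2] - 1) / 2
  g <- expand.grid(y = 0:(d[2] - 1), x = 0:(d[3] - 1))
  xo <- g$x - cx; yo <- g$y - cy
  if (draw$fh) xo <- -xo
  if (draw$fv) yo <- -yo
  # inverse map: undo shift, zoom, rotation
  xr <- (cos(-draw$rot) * xo - sin(-draw$rot) * yo) / draw$zoom
  yr <- (sin(-draw$rot) * xo + cos(-draw$rot) * yo) / draw$zoom
  xq <- xr + cx - draw$sx
  yq <- yr + cy - draw$sy
  out <- array(0, d)
  for (i in seq_len(d[1])) {
    v <- bilinear_sample(clip[i, , ], xq, yq)
    out[i, , ] <- matrix(v, d[2], d[3])
  }
  clamp(out, 0, 255)
}

# Is an identity draw? (used to short-circuit and keep identity exact)
is_identity_draw <- function(draw) {
  draw$sx == 0 && draw$sy == 0 && draw$zoom == 1 && draw$rot == 0 &&
    !draw$fh && !draw$fv
}

#' Generate a labelled clip library from synthetic movies
#'
#' Renders as many movies as needed (seeds derived from `config$seed`) and
#' cuts 59x59 clip sequences: label 1 centred on apoptotic events (with a
#' small spatial jitter, covering one frame before the event through the
#' fragmentation), label 0 from healthy cells, random background locations
#' and, when the configuration includes mitotic confounders, mitotic cells.
#' A quarter of the label-0 clips are time-reversed apoptotic sequences, so
#' that temporal order (and not appearance alone) separates the classes.
#' Negative locations keep a safety margin from any concurrent event.
#'
#' @param config a [synth_config()] describing the library movies.
#' @param n_per_class number of label-1 clips.
#' @param neg_ratio negatives per positive (1 gives balanced classes, 10 the
#'   1:10 apoptotic-to-nonapoptotic training imbalance).
#' @param safety_radius_px minimum distance of a negative centre from an
#'   event active during the clip window.
#' @param jitter_px maximum absolute spatial jitter of positive centres.
#' @return A `clip_set`.
#' @export
generate_clip_library <- function(config, n_per_class, neg_ratio = 1,
                                  safety_radius_px = 40, jitter_px = 3L) {
  stopifnot(n_per_class >= 1)
  n_neg_target <- ceiling(n_per_class * neg_ratio)
  # temporal-order negatives: a quarter of label-0 clips are time-reversed
  # apoptotic sequences (they look like condensation run backwards, i.e. a
  # nonapoptotic appearance change); without them nothing forces the
  # classifier to use frame order, as appearance alone separates the classes
  n_rev_target <- ceiling(0.25 * n_neg_target)
  n_smp_target <- n_neg_target - n_rev_target
  pos <- neg <- rev_neg <- NULL
  movie_i <- 0L
  fade <- 4L
  while (is.null(pos) || length(pos) < n_per_class ||
         length(neg) < n_smp_target || length(rev_neg) < n_rev_target) {
    movie_i <- movie_i + 1L
    if (movie_i > 200L) stop("clip library generation did not converge")
    cfg <- config
    cfg$seed <- derive_seed(config$seed, movie_i)
    sm <- generate_movie(cfg)
    D <- cfg$event_duration_frames
    rng_seed <- derive_seed(cfg$seed, 999L)
    res <- with_seed(rng_seed, {
      tr <- sm$truth
      jx <- sample(-jitter_px:jitter_px, nrow(tr), replace = TRUE)
      jy <- sample(-jitter_px:jitter_px, nrow(tr), replace = TRUE)
      p_clips <- lapply(seq_len(nrow(tr)), function(i)
        extract_clip(sm$movie, tr$x[i] + jx[i], tr$y[i] + jy[i],
                     (tr$t[i] - 1L):(tr$t[i] + D + 2L)))
      p <- new_clip_set(p_clips, rep(1L, nrow(tr)),
                        rep(sm$movie$source_id, nrow(tr)),
                        tr$t, tr$x + jx, tr$y + jy)
      n <- sample_negative_clips(sm, ceiling(n_smp_target / 2),
                                 safety_radius_px, D + fade)
      r <- new_clip_set(lapply(p_clips, function(cl)
        cl[rev(seq_len(dim(cl)[1])), , , drop = FALSE]),
        rep(0L, nrow(tr)), rep(sm$movie$source_id, nrow(tr)),
        tr$t, tr$x + jx, tr$y + jy)
      list(p = p, n = n, r = r)
    })
    pos <- if (is.null(pos)) res$p else clip_set_bind(pos, res$p)
    neg <- if (is.null(neg)) res$n else clip_set_bind(neg, res$n)
    rev_neg <- if (is.null(rev_neg)) res$r else clip_set_bind(rev_neg, res$r)
  }
  clip_set_bind(
    clip_set_subset(pos, seq_len(n_per_class)),
    clip_set_bind(clip_set_subset(rev_neg, seq_len(n_rev_target)),
                  clip_set_subset(neg, seq_len(n_smp_target))))
}

# Draw negatives from one synthetic movie: healthy cells, background, and
# mitotic confounders when present. Must be called inside with_seed().
sample_negative_clips <- function(sm, n_wanted, safety_radius_px, active_len) {
  movie <- sm$movie
  d <- dim(movie$frames)
  TT <- d[1]
  tr <- sm$truth
  clip_half <- 6L  # matches positive clip span
  ok_neg <- function(x, y, tc) {
    if (!nrow(tr)) return(TRUE)
    dd <- sqrt((tr$x - x)^2 + (tr$y - y)^2)
    overlap <- (tc + clip_half) >= (tr$t - 1L) &
      (tc - 1L) <= (tr$t + active_len)
    !any(dd < safety_radius_px & overlap)
  }
  healthy <- sm$truth_tracks[!sm$truth_tracks$apoptotic, ]
  cells <- unique(healthy$cell_id)
  out <- list(); meta <- list()
  tries <- 0L
  while (length(out) < n_wanted && tries < n_wanted * 30L) {
    tries <- tries + 1L
    kind <- runif(1)
    if (kind < 0.55 && length(cells)) {        # healthy cell
      ci <- sample(cells, 1L)
      hh <- healthy[healthy$cell_id == ci, ]
      row <- hh[sample.int(nrow(hh), 1L), ]
      x <- row$x + sample(-3:3, 1); y <- row$y + sample(-3:3, 1); tc <- row$t
    } else {                                    # background / debris
      x <- runif(1, 0, d[3] - 1); y <- runif(1, 0, d[2] - 1)
      tc <- sample.int(TT, 1L) - 1L
    }
    tc <- clamp(tc, 1L, TT - 2L)
    if (!ok_neg(x, y, tc)) next
    out[[length(out) + 1L]] <-
      extract_clip(movie, x, y, (tc - 1L):(tc + clip_half))
    meta[[length(meta) + 1L]] <- c(tc, x, y)
  }
  m <- do.call(rbind, meta)
  if (is.null(m)) m <- matrix(numeric(0), 0, 3)
  new_clip_set(out, rep(0L, length(out)),
               rep(movie$source_id, length(out)), m[, 1], m[, 2], m[, 3])
}

#' Assemble training and validation splits
#'
#' Draws negatives to honour the requested class ratio, then either splits by
#' a validation fraction or returns movie-wise cross-validation folds (folds
#' never share a `movie_id` between training and validation).
#'
#' @param positives,negatives `clip_set`s of label 1 / label 0 clips.
#' @param ratio negatives per positive (10 reproduces the 1:10 training
#'   imbalance; 1 gives balanced classes).
#' @param val_fraction validation fraction (default 0.12) when `folds` is
#'   `NULL`.
#' @param folds if given, number of movie-wise cross-validation folds.
#' @param seed RNG seed for sampling and shuffling.
#' @return `list(train =, val =)` of `clip_set`s, or a list of such lists
#'   (one per fold).
#' @export
assemble_training_set <- function(positives, negatives, ratio = 1,
                                  val_fraction = 0.12, folds = NULL,
                                  seed = 1L) {
  stopifnot(all(positives$label == 1L), all(negatives$label == 0L))
  n_neg <- ceiling(length(positives) * ratio)
  if (length(negatives) < n_neg)
    stop("not enough negatives for a 1:", ratio, " ratio (need ", n_neg, ")")
  with_seed(seed, {
    neg <- clip_set_subset(negatives, sample.int(length(negatives), n_neg))
    all <- clip_set_bind(positives, neg)
    if (is.null(folds)) {
      idx <- sample.int(length(all))
      n_val <- max(1L, round(val_fraction * length(all)))
      list(val = clip_set_subset(all, idx[seq_len(n_val)]),
           train = clip_set_subset(all, idx[-seq_len(n_val)]))
    } else {
      movies <- unique(all$movie_id)
      fold_of <- setNames(rep(seq_len(folds), length.out = length(movies))[
        sample.int(length(movies))], movies)
      lapply(seq_len(folds), function(f) {
        vi <- which(fold_of[all$movie_id] == f)
        list(val = clip_set_subset(all, vi),
             train = clip_set_subset(all, setdiff(seq_len(length(all)), vi)))
      })
    }
  })
}

#' Mine hard negatives from event-free control movies
#'
#' Runs the full detection pipeline on control movies that contain no
#' apoptotic events; every detection is by construction a false positive and
#' is exported as a label-0 clip for retraining. This is the mechanism used
#' to populate the nonapoptotic class with the detector's own confusions.
#'
#' @param model a trained classifier (see [train_model()]).
#' @param control_movies list of event-free [timelapse()] movies.
#' @param cfg a [pipeline_config()].
#' @return A `clip_set` of label-0 clips (possibly empty).
#' @export
mine_hard_negatives <- function(model, control_movies, cfg = pipeline_config()) {
  sets <- lapply(control_movies, function(movie) {
    det <- detect_events(movie, model, cfg)
    if (!nrow(det)) return(NULL)
    half <- cfg$window_frames %/% 2L
    clips <- lapply(seq_len(nrow(det)), function(i)
      extract_clip(movie, (det$x_min[i] + det$x_max[i]) / 2,
                   (det$y_min[i] + det$y_max[i]) / 2,
                   (det$t[i] - half):(det$t[i] + half)))
    new_clip_set(clips, rep(0L, nrow(det)),
                 rep(movie$source_id, nrow(det)), det$t,
                 (det$x_min + det$x_max) / 2, (det$y_min + det$y_max) / 2)
  })
  sets <- Filter(Negate(is.null), sets)
  if (!length(sets))
    return(new_clip_set(list(), integer(0), character(0), integer(0),
                        numeric(0), numeric(0)))
  Reduce(clip_set_bind, sets)
}

#' Write / read a clip library on disk
#'
#' One grayscale 8-bit TIFF per clip (pages = frames) plus an index CSV with
#' columns `path,label,movie_id,center_t`.
#'
#' @param cs a `clip_set`.
#' @param dir output directory (created if needed).
#' @return The index CSV path ([write_clip_library()]) or a `clip_set`
#'   ([read_clip_library()]).
#' @export
write_clip_library <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("clip_%05d.tif", seq_along(cs$clips))
  for (i in seq_along(cs$clips)) {
    cl <- cs$clips[[i]]
    pages <- lapply(seq_len(dim(cl)[1]), function(k) cl[k, , ] / 255)
    tiff::writeTIFF(pages, file.path(dir, paths[i]), bits.per.sample = 8)
  }
  idx <- data.frame(path = paths, label = cs$label, movie_id = cs$movie_id,
                    center_t = cs$center_t)
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(file.path(dir, "index.csv"))
}

#' @rdname write_clip_library
#' @export
read_clip_library <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"))
  clips <- lapply(idx$path, function(p) {
    pages <- tiff::readTIFF(file.path(dir, p), all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    aperm(simplify2array(pages), c(3, 1, 2))
  })
  new_clip_set(clips, idx$label, idx$movie_id, idx$center_t,
               rep(NA_real_, nrow(idx)), rep(NA_real_, nrow(idx)))
}
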