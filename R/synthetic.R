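#' Synthetic movie configuration
#'
#' Parameters of the ground-truthed movie generator. Two phenotypes are
#' emulated: `in_vitro` renders a near-confluent monolayer of labelled nuclei
#' in which apoptotic cells shrink and condense (area down, peak intensity and
#' pixel-intensity SD up) over `event_duration_frames` and then fragment into
#' 2-4 fading apoptotic bodies; `in_vivo` renders sparse motile cells that
#' arrest, deform and fragment. Cells are drawn as anisotropic 2D Gaussians
#' with a mild sinusoidal texture; all randomness flows from `seed`.
#'
#' @param mode `"in_vitro"` or `"in_vivo"`.
#' @param H,W,T movie dimensions (pixels, frames).
#' @param n_cells number of cells placed in the field.
#' @param n_apoptoses number of apoptotic events (`<= n_cells`).
#' @param cell_radius_px mean nuclear/cell radius in pixels.
#' @param cell_radius_sd SD of the radius across cells.
#' @param motility_px_per_frame Brownian step SD (0 for the nonmotile
#'   in vitro monolayer).
#' @param noise_sd additive Gaussian noise SD on the 8-bit scale.
#' @param background_level mean background intensity (8-bit).
#' @param amplitude peak intensity of a healthy cell above background (8-bit).
#' @param event_duration_frames duration of the morphological changes; the
#'   default of 8 frames is the median event duration observed in vivo.
#' @param n_mitoses optional number of mitotic confounders (one nucleus
#'   splitting into two persistent nuclei), exercising the known
#'   false-positive mode of the detector.
#' @param frame_interval minutes per frame.
#' @param pixel_size micrometers per pixel.
#' @param target_snr optional; when set, `noise_sd` is recalibrated so the
#'   foreground-mean / background-SD ratio of the rendered movie matches it.
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(mode = c("in_vitro", "in_vivo"),
                         H = 256L, W = 256L, T = 100L,
                         n_cells = if (mode[1] == "in_vitro") 100L else 25L,
                         n_apoptoses = if (mode[1] == "in_vitro") 30L else 5L,
                         cell_radius_px = 5.5, cell_radius_sd = 0.7,
                         motility_px_per_frame = if (mode[1] == "in_vitro") 0 else 1.5,
                         noise_sd = 4, background_level = 32, amplitude = 170,
                         event_duration_frames = 8L, n_mitoses = 0L,
                         frame_interval = 5, pixel_size = 1,
                         target_snr = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_apoptoses <= n_cells, H > 0, W > 0, T > 0,
            event_duration_frames >= 2L,
            T > event_duration_frames + 2L)
  structure(as.list(environment()), class = "synth_config")
}

# Accumulate an anisotropic Gaussian cell stamp into a frame matrix (H x W,
# row = y). cx, cy are 0-based centers. Returns the modified frame.
stamp_cell <- function(frame, cx, cy, sx, sy, theta, amp, tex = NULL) {
  H <- nrow(frame); W <- ncol(frame)
  r <- ceiling(3.2 * max(sx, sy))
  xs <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(frame)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  g <- amp * exp(-0.5 * ((u / sx)^2 + (v / sy)^2))
  if (!is.null(tex))
    g <- g * (1 + tex$amp * sin(2 * pi * (tex$fx * dx + tex$fy * dy) + tex$phase))
  frame[ys + 1, xs + 1] <- frame[ys + 1, xs + 1] + g
  frame
}

# Place n cell centers with minimum separation by dart throwing.
place_cells <- function(n, H, W, min_sep, margin = 6, max_tries = 20000L) {
  xs <- numeric(0); ys <- numeric(0); tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " cells without overlap; reduce n_cells")
    x <- runif(1, margin, W - 1 - margin)
    y <- runif(1, margin, H - 1 - margin)
    if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys)
}

#' Generate a ground-truthed synthetic movie
#'
#' Renders a movie per the configuration and returns it together with the
#' ground truth: one annotation per apoptotic event at the event start (the
#' beginning of shrinkage, matching how real events are annotated) and the
#' full per-cell trajectories. The same seed yields a bit-identical movie.
#'
#' @param config a [synth_config()].
#' @return A list of class `synthetic_movie` with elements `movie`
#'   ([timelapse()]), `truth` (data frame `x, y, t, label, track_id`, plus
#'   `t_disrupt`, the frame of peak condensation right before fragmentation)
#'   and `truth_tracks` (data frame `cell_id, t, x, y, apoptotic`).
#' @export
generate_movie <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_movie_impl(config))
}

generate_movie_impl <- function(cfg) {
  H <- cfg$H; W <- cfg$W; TT <- cfg$T; D <- cfg$event_duration_frames
  n <- cfg$n_cells
  sep <- if (cfg$mode == "in_vitro") 2.6 * cfg$cell_radius_px else 5 * cfg$cell_radius_px
  cells <- place_cells(n, H, W, sep)
  cells$r <- pmax(2.5, rnorm(n, cfg$cell_radius_px, cfg$cell_radius_sd))
  cells$aspect <- runif(n, 0.8, 1.25)
  cells$theta <- runif(n, 0, pi)
  cells$amp <- cfg$amplitude * runif(n, 0.85, 1.15)
  tex <- lapply(seq_len(n), function(i)
    list(amp = 0.12, fx = runif(1, 0.08, 0.2), fy = runif(1, 0.08, 0.2),
         phase = runif(1, 0, 2 * pi)))

  apo <- sort(sample.int(n, cfg$n_apoptoses))
  fade <- 4L
  t0 <- sample(seq.int(2L, TT - D - 2L), cfg$n_apoptoses, replace = TRUE)
  ev <- setNames(rep(NA_integer_, n), NULL); ev[apo] <- t0
  frag <- vector("list", n)
  for (i in apo) {
    k <- sample(2:4, 1)
    ang <- runif(k, 0, 2 * pi)
    dist <- runif(k, 0.5, 1.5) * cells$r[i]
    frag[[i]] <- data.frame(dx = cos(ang) * dist, dy = sin(ang) * dist,
                            r = cells$r[i] * 0.35 * runif(k, 0.8, 1.2))
  }
  mito <- integer(0)
  if (cfg$n_mitoses > 0) {
    pool <- setdiff(seq_len(n), apo)
    mito <- sample(pool, min(cfg$n_mitoses, length(pool)))
  }
  tm <- setNames(rep(NA_integer_, n), NULL)
  mang <- runif(n, 0, 2 * pi)
  if (length(mito)) tm[mito] <- sample(seq.int(2L, TT - 8L), length(mito),
                                       replace = TRUE)

  # precompute Brownian paths (arrest at event start for apoptotic cells)
  px <- matrix(cells$x, TT, n, byrow = TRUE)
  py <- matrix(cells$y, TT, n, byrow = TRUE)
  if (cfg$motility_px_per_frame > 0) {
    for (t in 2:TT) {
      step_x <- rnorm(n, 0, cfg$motility_px_per_frame)
      step_y <- rnorm(n, 0, cfg$motility_px_per_frame)
      frozen <- !is.na(ev) & (t - 1L) >= ev
      step_x[frozen] <- 0; step_y[frozen] <- 0
      px[t, ] <- clamp(px[t - 1, ] + step_x, 4, W - 5)
      py[t, ] <- clamp(py[t - 1, ] + step_y, 4, H - 5)
    }
  }

  frames <- array(0, c(TT, H, W))
  noise <- if (cfg$noise_sd > 0)
    array(rnorm(TT * H * W, 0, cfg$noise_sd), c(TT, H, W)) else 0
  for (t in seq_len(TT)) {
    fr <- matrix(cfg$background_level, H, W)
    tt0 <- t - 1L  # 0-based frame
    for (i in seq_len(n)) {
      r <- cells$r[i]; amp <- cells$amp[i] * (1 + 0.03 * sin(t / 3 + i))
      sx <- r / 1.6 * cells$aspect[i]; sy <- r / 1.6 / cells$aspect[i]
      cx <- px[t, i]; cy <- py[t, i]
      if (!is.na(ev[i]) && tt0 >= ev[i]) {
        u <- (tt0 - ev[i]) / (D - 1)
        if (u <= 1) {  # shrinkage + condensation (area falls to ~40%)
          shrink <- 1 - 0.35 * min(u, 1)
          fr <- stamp_cell(fr, cx, cy, sx * shrink, sy * shrink, cells$theta[i],
                           amp * (1 + 0.9 * u), tex[[i]])
        } else {       # fragmentation into fading bodies
          s <- tt0 - ev[i] - (D - 1)
          if (s <= fade) {
            fb <- frag[[i]]
            a <- 1.4 * amp * (1 - s / (fade + 1))
            for (j in seq_len(nrow(fb)))
              fr <- stamp_cell(fr, cx + fb$dx[j], cy + fb$dy[j],
                               fb$r[j] / 1.4, fb$r[j] / 1.4, 0, a)
          }
        }
      } else if (!is.na(tm[i]) && tt0 >= tm[i]) {
        # mitotic confounder: elongate then split into two persistent nuclei
        s <- tt0 - tm[i]
        if (s < 3) {
          fr <- stamp_cell(fr, cx, cy, sx * (1 + 0.35 * s), sy * 0.9,
                           mang[i], amp * 1.15, tex[[i]])
        } else {
          off <- min(3 + 0.6 * (s - 3), 2.4 * r)
          for (sgn in c(-1, 1))
            fr <- stamp_cell(fr, cx + sgn * off * cos(mang[i]),
                             cy + sgn * off * sin(mang[i]),
                             sx * 0.8, sy * 0.8, cells$theta[i], amp * 0.95,
                             tex[[i]])
        }
      } else {
        if (cfg$mode == "in_vivo") {
          # mild shape fluctuation of motile cells
          w <- 1 + 0.15 * sin(t / 2 + i * 1.7)
          fr <- stamp_cell(fr, cx, cy, sx * w, sy / w, cells$theta[i], amp,
                           tex[[i]])
        } else {
          fr <- stamp_cell(fr, cx, cy, sx, sy, cells$theta[i], amp, tex[[i]])
        }
      }
    }
    frames[t, , ] <- fr
  }
  frames <- floor(clamp(frames + noise, 0, 255))
  movie <- timelapse(frames, 8L, cfg$frame_interval, cfg$pixel_size,
                     sprintf("synth-%s-seed%d", cfg$mode, cfg$seed))
  truth <- data.frame(x = round(cells$x[apo]), y = round(cells$y[apo]),
                      t = t0, label = 1L, track_id = apo,
                      t_disrupt = t0 + D - 1L)
  tr <- do.call(rbind, lapply(seq_len(n), function(i) {
    last <- if (!is.na(ev[i])) min(TT - 1L, ev[i] + D - 1L + fade) else TT - 1L
    tt <- 0:last
    data.frame(cell_id = i, t = tt, x = px[tt + 1, i], y = py[tt + 1, i],
               apoptotic = !is.na(ev[i]))
  }))
  structure(list(movie = movie, truth = truth, truth_tracks = tr,
                 config = cfg),
            class = "synthetic_movie")
}

#' Calibrate generator noise to a target signal-to-noise ratio
#'
#' Renders a noise-free frame, measures the Otsu-foreground mean, and returns
#' a copy of the configuration with `noise_sd` set so that
#' foreground mean / background SD equals `target_snr`.
#'
#' @param config a [synth_config()] with `target_snr` set (or passed here).
#' @param target_snr the desired SNR.
#' @return The adjusted `synth_config`.
#' @export
calibrate_snr <- function(config, target_snr = config$target_snr) {
  stopifnot(!is.null(target_snr), target_snr > 0)
  quiet <- config
  quiet$noise_sd <- 0
  sm <- generate_movie(quiet)
  mid <- sm$movie$frames[ceiling(dim(sm$movie$frames)[1] / 2), , ]
  thr <- EBImage::otsu(EBImage::Image(mid / 255), range = c(0, 1)) * 255
  fg_mean <- mean(mid[mid > thr])
  config$noise_sd <- fg_mean / target_snr
  config$target_snr <- target_snr
  config
}
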