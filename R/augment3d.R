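# 3D rotation augmentation for volumetric (light-sheet style) recordings:
# rotate the volume about a random axis, max-project, and crop to the
# classifier input size, multiplying each annotated event sequence into many
# training samples.

# Resample a Z x H x W volume to isotropic voxels by integer-factor linear
# interpolation along z. The factor is ceiling(z_spacing / pixel_size), so
# the original slice positions are a subset of the output grid: at angle 0
# the projection of the resampled volume equals the projection of the input
# (linear interpolation between two slices never exceeds either neighbour,
# so interpolated slices cannot change the per-pixel maximum).
resample_isotropic <- function(vol, z_spacing, pixel_size) {
  f <- as.integer(ceiling(z_spacing / pixel_size))
  if (f <= 1L) return(list(vol = vol, factor = 1L))
  Z <- dim(vol)[1]
  nz <- (Z - 1L) * f + 1L
  out <- array(0, c(nz, dim(vol)[2], dim(vol)[3]))
  for (i in seq_len(Z - 1L)) {
    for (j in 0:(f - 1L)) {
      w <- j / f
      out[(i - 1L) * f + j + 1L, , ] <- (1 - w) * vol[i, , ] + w * vol[i + 1L, , ]
    }
  }
  out[nz, , ] <- vol[Z, , ]
  list(vol = out, factor = f)
}

# Rodrigues rotation matrix for a unit axis and angle in radians.
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Trilinear sample of vol (Z x H x W) at 0-based coordinates; out-of-volume
# points take `fill`.
trilinear_sample <- function(vol, z, y, x, fill) {
  dz <- dim(vol)[1]; dy <- dim(vol)[2]; dx <- dim(vol)[3]
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  val <- numeric(length(z))
  get <- function(zz, yy, xx) {
    ok <- zz >= 0 & zz <= dz - 1 & yy >= 0 & yy <= dy - 1 &
      xx >= 0 & xx <= dx - 1
    v <- rep(fill, length(zz))
    if (any(ok))
      v[ok] <- vol[cbind(zz[ok] + 1, yy[ok] + 1, xx[ok] + 1)]
    v
  }
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cz) fz else 1 - fz) * (if (cy) fy else 1 - fy) *
      (if (cx) fx else 1 - fx)
    val <- val + w * get(z0 + cz, y0 + cy, x0 + cx)
  }
  val
}

#' Rotate a volumetric sequence and maximum-project it
#'
#' For each time point the Z-stack is resampled to isotropic voxels, rotated
#' about `axis` by `angle` degrees around the volume centre (empty space
#' filled with the volume's median intensity), projected along z by per-pixel
#' maximum, and centre-cropped (or symmetrically padded) to `out_size`
#' pixels. At `angle = 0` the output equals the plain maximum projection of
#' the input crop.
#'
#' @param vol_movie a [volumetric_timelapse()] (frames `T x Z x H x W`).
#' @param angle rotation angle in degrees.
#' @param axis length-3 rotation axis `(x, y, z)` (any norm).
#' @param out_size output edge in pixels (classifier input size by default).
#' @return `T x out_size x out_size` array.
#' @export
rotate_project <- function(vol_movie, angle, axis = c(0, 0, 1),
                           out_size = 59L) {
  stopifnot(inherits(vol_movie, "volumetric_timelapse"))
  d <- dim(vol_movie$frames)
  TT <- d[1]
  iso <- NULL
  out <- array(0, c(TT, out_size, out_size))
  R <- rotation_matrix(axis, angle * pi / 180)
  Rinv <- t(R)                       # rotation matrices: inverse = transpose
  for (tt in seq_len(TT)) {
    vol <- resample_isotropic(vol_movie$frames[tt, , , ],
                              vol_movie$z_spacing %||% 1,
                              vol_movie$pixel_size %||% 1)$vol
    dz <- dim(vol)[1]; dy <- dim(vol)[2]; dx <- dim(vol)[3]
    fill <- median(vol)
    cz <- (dz - 1) / 2; cy <- (dy - 1) / 2; cx <- (dx - 1) / 2
    if (angle == 0) {
      proj <- apply(vol, c(2, 3), max)
    } else {
      grid <- expand.grid(z = 0:(dz - 1), y = 0:(dy - 1), x = 0:(dx - 1))
      # target coords -> source coords via the inverse rotation (x, y, z order)
      pts <- rbind(grid$x - cx, grid$y - cy, grid$z - cz)
      src <- Rinv %*% pts
      vals <- trilinear_sample(vol, src[3, ] + cz, src[2, ] + cy,
                               src[1, ] + cx, fill)
      rot <- array(vals, c(dz, dy, dx))
      proj <- apply(rot, c(2, 3), max)
    }
    out[tt, , ] <- fit_to_size(proj, out_size)
  }
  out
}

# Centre-crop or symmetric-reflect pad a matrix to size x size.
fit_to_size <- function(m, size) {
  H <- nrow(m); W <- ncol(m)
  ys <- fit_axis(H, size)
  xs <- fit_axis(W, size)
  m[ys, xs]
}

fit_axis <- function(n, size) {
  if (n >= size) {
    start <- (n - size) %/% 2L + 1L
    start:(start + size - 1L)
  } else {
    off <- (size - n) %/% 2L
    sym_index(seq_len(size) - 1L - off, n) + 1L
  }
}

#' Expand a volumetric clip library by random 3D rotations
#'
#' Each annotated sequence is rendered `k` times with an independently drawn
#' rotation: angle uniform in `[0, max_angle]` degrees and axis uniform on
#' the sphere. With the published setting (`max_angle = 45`, `k = 100`) a
#' library of n sequences becomes `k * n` training clips.
#'
#' @param volumes list of [volumetric_timelapse()] sequences.
#' @param labels integer labels (0/1), one per sequence.
#' @param k augmentation factor per sequence.
#' @param max_angle maximum rotation angle in degrees.
#' @param out_size output clip edge in pixels.
#' @param seed RNG seed.
#' @return A `clip_set` of `k * length(volumes)` clips; draw parameters are
#'   attached as attribute `draws` (data frame `source, angle, ax, ay, az`).
#' @export
expand_dataset <- function(volumes, labels, k = 100L, max_angle = 45,
                           out_size = 59L, seed = 1L) {
  stopifnot(length(volumes) == length(labels), k >= 1L)
  with_seed(seed, {
    draws <- data.frame(source = rep(seq_along(volumes), each = k),
                        angle = numeric(k * length(volumes)),
                        ax = 0, ay = 0, az = 0)
    clips <- vector("list", k * length(volumes))
    for (r in seq_len(nrow(draws))) {
      angle <- runif(1, 0, max_angle)
      # uniform direction on the sphere
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      draws$angle[r] <- angle
      draws[r, c("ax", "ay", "az")] <- v
      clips[[r]] <- rotate_project(volumes[[draws$source[r]]], angle, v,
                                   out_size)
    }
    cs <- new_clip_set(clips, labels[draws$source], draws$source,
                       rep(0L, nrow(draws)),
                       rep((out_size - 1) / 2, nrow(draws)),
                       rep((out_size - 1) / 2, nrow(draws)))
    attr(cs, "draws") <- draws
    cs
  })
}
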