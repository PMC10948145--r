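test_that("extract_clip produces 59x59 windows and reflects at borders", {
  tl <- toy_movie(6, 70, 70, seed = 1)
  cl <- extract_clip(tl, 35, 35, c(0, 2, 4))
  expect_equal(dim(cl), c(3, 59, 59))
  # interior: clip centre pixel equals the movie pixel at (x, y)
  expect_equal(cl[2, 30, 30], tl$frames[3, 36, 36])
  # border: half-sample reflection, x = -1 -> 0, x = -2 -> 1
  cb <- extract_clip(tl, 0, 35, 0)
  expect_equal(cb[1, 30, 30], tl$frames[1, 36, 1]) # centre pixel is (0, 35)
  expect_equal(cb[1, , 29], cb[1, , 30])           # x = -1 reflects to 0
  expect_equal(cb[1, , 28], cb[1, , 31])           # x = -2 reflects to 1
  # frame indices clamp to the movie
  ce <- extract_clip(tl, 35, 35, c(-5, 0))
  expect_equal(ce[1, , ], ce[2, , ])
  expect_error(extract_clip(toy_movie(2, 30, 30), 10, 10, 0), "smaller")
})

test_that("crop frame offsets follow the documented minute spacing", {
  # -10..50 min in 7 steps at 5 min/frame: (-2, 0, 2, 4, 6, 8, 10)
  expect_equal(crop_frame_offsets(5), c(-2L, 0L, 2L, 4L, 6L, 8L, 10L))
  # 10 min/frame: minutes (-10, 0, 10, 20, 30, 40, 50) -> (-1, 0, 1, ..., 5)
  expect_equal(crop_frame_offsets(10), -1:5)
  tl <- toy_movie(20, 60, 60, seed = 2)
  cs <- extract_training_crops(tl, data.frame(x = 30, y = 30, t = 5L))
  expect_equal(length(cs), 1L)
  expect_equal(dim(cs$clips[[1]]), c(7, 59, 59))
  expect_equal(cs$label, 1L)
})

test_that("sample_fixed_length keeps endpoints and handles short clips", {
  cl <- array(seq_len(9 * 4 * 4), c(9, 4, 4))
  s <- sample_fixed_length(cl, 5L)
  expect_equal(dim(s), c(5, 4, 4))
  expect_equal(s[1, , ], cl[1, , ])
  expect_equal(s[5, , ], cl[9, , ])
  short <- array(seq_len(2 * 4 * 4), c(2, 4, 4))
  s2 <- sample_fixed_length(short, 5L)
  expect_equal(dim(s2), c(5, 4, 4))
  expect_equal(s2[1, , ], short[1, , ])
  expect_equal(s2[5, , ], short[2, , ])
})

test_that("augment2d identity draw reproduces the clip; flips are exact", {
  cl <- apodetect:::with_seed(3, array(sample(0:255, 5 * 20 * 20, TRUE),
                                       c(5, 20, 20)))
  idd <- list(sx = 0, sy = 0, zoom = 1, rot = 0, fh = FALSE, fv = FALSE)
  expect_equal(apodetect:::apply_affine_clip(cl, idd), cl)
  hd <- utils::modifyList(idd, list(fh = TRUE))
  fl <- apodetect:::apply_affine_clip(cl, hd)
  expect_equal(fl, cl[, , 20:1, drop = FALSE], ignore_attr = TRUE)
  vd <- utils::modifyList(idd, list(fv = TRUE))
  expect_equal(apodetect:::apply_affine_clip(cl, vd),
               cl[, 20:1, , drop = FALSE], ignore_attr = TRUE)
  # a random draw is reproducible for the same seed and stays in range
  a <- augment2d(cl, seed = 7L)
  b <- augment2d(cl, seed = 7L)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 255))
  expect_equal(dim(a), dim(cl))
})

test_that("clip library honours the class ratio and label composition", {
  cfg <- synth_config(H = 128L, W = 128L, T = 24L, n_cells = 12L,
                      n_apoptoses = 4L, seed = 21L)
  lib <- generate_clip_library(cfg, n_per_class = 12L, neg_ratio = 2)
  expect_equal(sum(lib$label == 1L), 12L)
  expect_equal(sum(lib$label == 0L), 24L)
  expect_true(all(vapply(lib$clips, function(cl)
    all(dim(cl)[2:3] == c(59, 59)), logical(1))))
  # reversed-positive negatives: the first quarter of the label-0 clips are
  # frame-reversed apoptotic sequences, so at least one label-0 clip must be
  # the exact reversal of a label-1 clip from the same movie
  pos <- lib$clips[lib$label == 1L]
  negs <- lib$clips[lib$label == 0L]
  rev_of <- function(cl) cl[rev(seq_len(dim(cl)[1])), , , drop = FALSE]
  found <- any(vapply(negs, function(ng)
    any(vapply(pos, function(p) identical(rev_of(p), ng), logical(1))),
    logical(1)))
  expect_true(found)
})

test_that("assemble_training_set ratio, split size and determinism", {
  cfg <- synth_config(H = 128L, W = 128L, T = 24L, n_cells = 12L,
                      n_apoptoses = 4L, seed = 22L)
  lib <- generate_clip_library(cfg, n_per_class = 10L, neg_ratio = 3)
  pos <- apodetect:::clip_set_subset(lib, which(lib$label == 1L))
  neg <- apodetect:::clip_set_subset(lib, which(lib$label == 0L))
  sp <- assemble_training_set(pos, neg, ratio = 2, val_fraction = 0.12,
                              seed = 5L)
  n_all <- 10L + 20L
  expect_equal(length(sp$train) + length(sp$val), n_all)
  expect_equal(length(sp$val), max(1L, round(0.12 * n_all)))
  sp2 <- assemble_training_set(pos, neg, ratio = 2, val_fraction = 0.12,
                               seed = 5L)
  expect_identical(sp$val$clips, sp2$val$clips)
  expect_error(assemble_training_set(pos, neg, ratio = 10), "not enough")
})

test_that("cross-validation folds never share a movie across the split", {
  sets <- lapply(1:4, function(i) {
    cfg <- synth_config(H = 96L, W = 96L, T = 20L, n_cells = 6L,
                        n_apoptoses = 2L, seed = 30L + i)
    sm <- generate_movie(cfg)
    extract_training_crops(sm$movie, sm$truth[, c("x", "y", "t")])
  })
  pos <- Reduce(apodetect:::clip_set_bind, sets)
  neg <- pos; neg$label <- rep(0L, length(neg))
  folds <- assemble_training_set(pos, neg, ratio = 1, folds = 2L, seed = 3L)
  expect_length(folds, 2L)
  for (f in folds) {
    expect_length(intersect(unique(f$train$movie_id),
                            unique(f$val$movie_id)), 0L)
    expect_equal(length(f$train) + length(f$val), 2L * length(pos))
  }
})

test_that("clip library round trips through disk", {
  tl <- toy_movie(8, 60, 60, seed = 4)
  cs <- extract_training_crops(tl, data.frame(x = c(30, 25), y = c(30, 35),
                                              t = c(2L, 3L),
                                              label = c(1L, 0L)))
  d <- withr::local_tempdir()
  write_clip_library(cs, d)
  back <- read_clip_library(d)
  expect_equal(length(back), 2L)
  expect_equal(back$label, cs$label)
  expect_equal(back$clips[[1]], cs$clips[[1]])
  expect_equal(back$clips[[2]], cs$clips[[2]])
})
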