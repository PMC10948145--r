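test_that("filter_boxes matches a literal oracle and keeps boundaries", {
  fr <- matrix(0, 80, 80)
  fr[11:40, 11:40] <- 120   # bright 30x30 block
  boxes <- data.frame(
    x_min = c(10L, 10L, 10L, 50L, 0L, 10L),
    y_min = c(10L, 10L, 10L, 50L, 0L, 10L),
    x_max = c(40L, 29L, 51L, 70L, 20L, 30L),  # edges 30, 19, 41, 20, 20, 20
    y_max = c(40L, 29L, 51L, 70L, 20L, 30L))
  out <- filter_boxes(boxes, fr)
  # oracle: both edges in [20, 40] inclusive AND mean >= 40
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    ex <- boxes$x_max[i] - boxes$x_min[i]
    ey <- boxes$y_max[i] - boxes$y_min[i]
    m <- mean(fr[(boxes$y_min[i] + 1):boxes$y_max[i],
                 (boxes$x_min[i] + 1):boxes$x_max[i]])
    keep[i] <- ex >= 20 && ex <= 40 && ey >= 20 && ey <= 40 && m >= 40
  }
  expect_equal(out[, 1:4], boxes[keep, ], ignore_attr = TRUE)
  # box 1 (edge 30, mean 120) and box 6 (edge 20, bright) survive; the dim
  # 20-edge box 5 and out-of-range edges do not
  expect_equal(rownames(out), c("1", "6"))
  # a box with mean exactly 40 is kept (exclusion is strictly below 40)
  fr2 <- matrix(40, 30, 30)
  b2 <- data.frame(x_min = 0L, y_min = 0L, x_max = 20L, y_max = 20L)
  expect_equal(nrow(filter_boxes(b2, fr2)), 1L)
  expect_equal(nrow(filter_boxes(b2, fr2 - 1)), 0L)
})

test_that("proposed boxes always lie inside the frame with legal edges", {
  for (seed in 1:3) {
    cfg <- synth_config(H = 128L, W = 128L, T = 12L, n_cells = 25L,
                        n_apoptoses = 5L, seed = seed)
    sm <- generate_movie(cfg)
    for (t in c(0L, 6L, 11L)) {
      fr <- sm$movie$frames[t + 1L, , ]
      for (method in c("blob", "selective")) {
        b <- propose_rois(fr, proposal_config(method = method))
        if (!nrow(b)) next
        expect_true(all(b$x_min >= 0 & b$y_min >= 0))
        expect_true(all(b$x_max <= 128 & b$y_max <= 128))
        expect_true(all(b$x_max - b$x_min >= 20 & b$x_max - b$x_min <= 40))
        expect_true(all(b$y_max - b$y_min >= 20 & b$y_max - b$y_min <= 40))
        expect_true(all(b$mean_intensity >= 40))
      }
    }
  }
})

test_that("blob proposer recalls at least 95% of visible cells", {
  hits <- 0L; total <- 0L
  for (seed in 11:13) {
    cfg <- synth_config(H = 192L, W = 192L, T = 12L, n_cells = 40L,
                        n_apoptoses = 8L, seed = seed)
    sm <- generate_movie(cfg)
    tr <- sm$truth_tracks
    for (t in c(0L, 5L)) {
      fr <- sm$movie$frames[t + 1L, , ]
      b <- propose_rois(fr, proposal_config())
      pos <- tr[tr$t == t, ]
      for (i in seq_len(nrow(pos))) {
        total <- total + 1L
        inside <- b$x_min <= pos$x[i] & pos$x[i] < b$x_max &
          b$y_min <= pos$y[i] & pos$y[i] < b$y_max
        if (any(inside)) hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("an empty frame yields no proposals", {
  fr <- matrix(5, 64, 64)
  expect_equal(nrow(propose_rois(fr, proposal_config())), 0L)
  noisy <- apodetect:::with_seed(1, matrix(pmax(0, rnorm(64 * 64, 5, 2)), 64))
  expect_equal(nrow(propose_rois(noisy, proposal_config())), 0L)
})

test_that("selective proposer finds an isolated bright cell", {
  fr <- matrix(8, 96, 96)
  fr <- apodetect:::with_seed(2, fr + matrix(abs(rnorm(96 * 96, 0, 2)), 96))
  ys <- 36:60; xs <- 56:80
  fr[ys, xs] <- fr[ys, xs] +
    150 * exp(-0.5 * (outer((ys - 48) / 6, rep(1, 25))^2 +
                        outer(rep(1, 25), (xs - 68) / 6)^2))
  b <- propose_rois(fr, proposal_config(method = "selective"))
  expect_gt(nrow(b), 0)
  inside <- b$x_min <= 68 & 68 < b$x_max & b$y_min <= 48 & 48 < b$y_max
  expect_true(any(inside))
})

test_that("centered_box stays within bounds at corners", {
  cb <- apodetect:::centered_box
  expect_equal(cb(0, 0, 20L, 100L, 100L), c(0, 0, 20, 20))
  expect_equal(cb(99, 99, 20L, 100L, 100L), c(80, 80, 100, 100))
  expect_equal(cb(50, 50, 21L, 100L, 100L), c(40, 40, 61, 61))
})
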