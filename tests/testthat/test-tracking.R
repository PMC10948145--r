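mkdet <- function(t, x, y, prob = 0.99) {
  data.frame(t = as.integer(t), x_min = round(x) - 10L, y_min = round(y) - 10L,
             x_max = round(x) + 10L, y_max = round(y) + 10L, prob = prob)
}

test_that("well-separated trajectories are recovered exactly", {
  truth <- list(a = cbind(0:9, 20 + 0.5 * (0:9), 20),
                b = cbind(0:9, 100, 100 + 0.8 * (0:9)),
                c = cbind(2:8, 160, 40))
  det <- do.call(rbind, lapply(truth, function(m) mkdet(m[, 1], m[, 2], m[, 3])))
  det <- det[order(det$t, det$x_min), ]
  tr <- track_detections(det)
  expect_equal(length(unique(tr$track_id)), 3L)
  # each recovered track contains exactly one truth trajectory's frames
  for (m in truth) {
    hit <- tr[abs(tr$x - m[1, 2]) < 6 & abs(tr$y - m[1, 3]) < 6 &
                tr$t == m[1, 1], ]
    expect_equal(nrow(hit), 1L)
    full <- tr[tr$track_id == hit$track_id, ]
    expect_equal(full$t, as.integer(m[, 1]))
    expect_equal(full$x, round(m[, 2]))
    expect_equal(full$y, round(m[, 3]))
  }
})

test_that("gap rule: reappearance within 3 missing frames keeps the id", {
  for (g in 0:3) {
    det <- rbind(mkdet(c(0, 1), 50, 50), mkdet(2 + g, 50, 50))
    tr <- track_detections(det, gap = 3L)
    expect_equal(length(unique(tr$track_id)), 1L)
    expect_equal(nrow(tr), 3L)
  }
})

test_that("gap rule: reappearance after 4 missing frames starts a new track", {
  det <- rbind(mkdet(c(0, 1), 50, 50), mkdet(c(6, 7), 50, 50))
  tr <- track_detections(det, gap = 3L)
  expect_equal(length(unique(tr$track_id)), 2L)
  # frames 0-1 and 6-7 are separate ids
  expect_equal(unique(tr$track_id[tr$t <= 1]), 1L)
  expect_equal(unique(tr$track_id[tr$t >= 6]), 2L)
})

test_that("distance threshold separates simultaneous nearby tracks", {
  det <- rbind(mkdet(0:4, 50, 50), mkdet(0:4, 50 + 15, 50))
  tr <- track_detections(det, dist_threshold = 10)
  expect_equal(length(unique(tr$track_id)), 2L)
  det2 <- rbind(mkdet(0, 50, 50), mkdet(1, 59, 50))  # step 9 < 10: same track
  tr2 <- track_detections(det2, dist_threshold = 10)
  expect_equal(length(unique(tr2$track_id)), 1L)
  det3 <- rbind(mkdet(0, 50, 50), mkdet(1, 61, 50))  # step 11 > 10: dropped
  expect_equal(nrow(track_detections(det3, dist_threshold = 10)), 0L)
})

test_that("tracks with fewer than 2 detections are dropped", {
  det <- rbind(mkdet(c(0, 1, 2), 30, 30), mkdet(5, 150, 150))
  tr <- track_detections(det)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_false(any(tr$x == 150))
  expect_true(all(table(tr$track_id) >= 2))
  expect_equal(nrow(track_detections(mkdet(0, 10, 10))), 0L)
  empty <- track_detections(mkdet(integer(0), numeric(0), numeric(0),
                                  prob = numeric(0)))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("track_id", "t", "x", "y", "prob"))
})

test_that("tracks_to_events summarizes start frame, median position, max prob", {
  tr <- data.frame(track_id = c(1L, 1L, 1L, 2L, 2L),
                   t = c(3L, 4L, 5L, 0L, 1L),
                   x = c(10, 12, 14, 50, 50),
                   y = c(20, 20, 26, 60, 62),
                   prob = c(0.7, 0.99, 0.8, 0.5, 0.6))
  ev <- tracks_to_events(tr)
  expect_equal(nrow(ev), 2L)
  e1 <- ev[ev$track_id == 1L, ]
  expect_equal(e1$t, 3L)
  expect_equal(e1$x, 12)
  expect_equal(e1$y, 20)
  expect_equal(e1$prob, 0.99)
  expect_equal(ev$t[ev$track_id == 2L], 0L)
})

test_that("track_kinematics computes speeds and reference distances", {
  trk <- data.frame(t = 0:3, x = c(0, 3, 3, 7), y = c(0, 4, 4, 7))
  k <- track_kinematics(trk, frame_interval = 2, pixel_size = 0.5)
  # steps: 5 px, 0 px, 5 px -> micrometers/min: 5*0.5/2
  expect_equal(k$speed$t, 1:3)
  expect_equal(k$speed$speed, c(1.25, 0, 1.25))
  k2 <- track_kinematics(trk, reference_point = c(0, 0))
  expect_equal(k2$distance$dist, c(0, 5, 5, sqrt(49 + 49)))
  expect_null(k$distance)
})
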