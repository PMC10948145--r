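test_that("match_events matches exactly and respects both radii", {
  truth <- data.frame(x = c(10, 100), y = c(10, 100), t = c(5L, 20L))
  # identical predictions: perfect score
  m <- match_events(truth, truth)
  expect_equal(m$tpr, 1)
  expect_equal(m$fpr, 0)
  expect_equal(m$matches$ds, c(0, 0))
  expect_equal(m$matches$dt, c(0, 0))
  # one prediction at the spatial boundary (20 px) is accepted, beyond is not
  p <- data.frame(x = 30, y = 10, t = 5L)
  expect_equal(match_events(p, truth)$tpr, 0.5)
  p2 <- data.frame(x = 30.5, y = 10, t = 5L)
  expect_equal(match_events(p2, truth)$tpr, 0)
  # temporal boundary: |dt| = 5 accepted, 6 rejected
  expect_equal(match_events(data.frame(x = 10, y = 10, t = 10L), truth)$tpr,
               0.5)
  expect_equal(match_events(data.frame(x = 10, y = 10, t = 11L), truth)$tpr,
               0)
  # one-to-one: two predictions cannot claim one truth event
  dup <- data.frame(x = c(10, 12), y = c(10, 10), t = c(5L, 5L))
  md <- match_events(dup, truth)
  expect_equal(nrow(md$matches), 1L)
  expect_equal(md$fpr, 0.5)
  # the closer prediction wins
  expect_equal(md$matches$pred, 1L)
  # empty inputs
  none <- data.frame(x = numeric(0), y = numeric(0), t = integer(0))
  expect_true(is.na(match_events(none, none)$tpr))
  expect_equal(match_events(none, truth)$tpr, 0)
})

test_that("nearest-neighbour distances equal the brute-force oracle", {
  for (seed in 1:3) {
    pts <- apodetect:::with_seed(seed, {
      list(pred = data.frame(x = runif(40, 0, 199), y = runif(40, 0, 199)),
           truth = data.frame(x = runif(15, 0, 199), y = runif(15, 0, 199)))
    })
    nn <- nn_analysis(pts$pred, pts$truth, c(10, 200, 200), seed = seed)
    oracle <- vapply(seq_len(40), function(i)
      min(sqrt((pts$truth$x - pts$pred$x[i])^2 +
                 (pts$truth$y - pts$pred$y[i])^2)), numeric(1))
    expect_equal(nn$distances, oracle)
    expect_equal(nn$mean_distance, mean(oracle))
    expect_length(nn$baseline, 40L)
    # baseline is reproducible for the same seed
    nn2 <- nn_analysis(pts$pred, pts$truth, c(10, 200, 200), seed = seed)
    expect_identical(nn$baseline, nn2$baseline)
  }
})

test_that("cumulative correlation is 1 for identical curves, NA when flat", {
  t1 <- c(2L, 5L, 5L, 9L)
  expect_equal(cumulative_correlation(t1, t1, 20L), 1)
  # shifted but proportional curves still correlate strongly, not perfectly
  r <- cumulative_correlation(t1 + 3L, t1, 20L)
  expect_true(r > 0.8 && r < 1)
  expect_true(is.na(cumulative_correlation(integer(0), t1, 20L)))
})

test_that("temporal offsets summarize matched pairs", {
  truth <- data.frame(x = c(10, 100), y = c(10, 100), t = c(5L, 20L))
  pred <- data.frame(x = c(10, 100), y = c(10, 100), t = c(7L, 19L))
  off <- temporal_offsets(match_events(pred, truth))
  expect_setequal(off$offsets, c(2L, -1L))
  expect_equal(off$mean, 0.5)
  expect_equal(off$mean_abs, 1.5)
})

test_that("TRA is 1 for identical tracks and 0 for an empty prediction", {
  tr <- data.frame(track_id = rep(1:2, c(3, 2)),
                   t = c(0L, 1L, 2L, 0L, 1L),
                   x = c(10, 10, 10, 50, 50), y = c(10, 10, 10, 50, 50))
  expect_equal(tra_score(tr, tr), 1)
  empty <- tr[0, ]
  expect_equal(tra_score(empty, tr), 0)
  expect_error(tra_score(tr, empty), "empty")
})

test_that("TRA reproduces a hand-enumerated 5-node AOGM case", {
  # truth: track 1 at (10,10) over t=0..2; track 2 at (50,50) over t=0..1
  # -> 5 nodes, 3 edges; AOGM_empty = 10*5 + 1.5*3 = 54.5
  truth <- data.frame(track_id = rep(1:2, c(3, 2)),
                      t = c(0L, 1L, 2L, 0L, 1L),
                      x = c(10, 10, 10, 50, 50), y = c(10, 10, 10, 50, 50))
  # prediction: recovers track 1 at t=0..1 (missing t=2), track 2 fully,
  # plus a spurious 2-node track at (90,90)
  pred <- data.frame(track_id = rep(1:3, each = 2),
                     t = rep(c(0L, 1L), 3),
                     x = c(10, 10, 50, 50, 90, 90),
                     y = c(10, 10, 50, 50, 90, 90))
  # edits: 1 missed node (10) + 2 spurious nodes (2*1) + 1 missing edge
  # (1.5) + 1 redundant edge (1) = 14.5
  expect_equal(tra_score(pred, truth), 1 - 14.5 / 54.5)
})

test_that("estimate_snr matches a direct computation and caps at 1000", {
  tl <- toy_movie(5, 40, 40, seed = 6)
  s <- estimate_snr(tl)
  expect_true(is.finite(s) && s > 0)
  flat <- timelapse(array(c(rep(10, 800 * 5), rep(200, 800 * 5)),
                          c(5, 40, 40)), bit_depth = 8L)
  expect_equal(estimate_snr(flat), 1000)
})

test_that("video quality score is in [0, 1] and ranks clean above crowded", {
  clean <- generate_movie(synth_config(H = 128L, W = 128L, T = 12L,
                                       n_cells = 8L, n_apoptoses = 2L,
                                       noise_sd = 2, seed = 61L))
  crowded <- generate_movie(synth_config(H = 128L, W = 128L, T = 12L,
                                         n_cells = 40L, n_apoptoses = 2L,
                                         noise_sd = 25, seed = 61L))
  qc <- video_quality_score(clean$movie)
  qx <- video_quality_score(crowded$movie)
  expect_true(qc$score >= 0 && qc$score <= 1)
  expect_true(qx$score >= 0 && qx$score <= 1)
  expect_gt(qc$score, qx$score)
  expect_named(qc$components,
               c("cell_count", "snr", "signal_sd", "min_distance",
                 "saturation"))
})

test_that("evaluate_events composes the report", {
  truth <- data.frame(x = c(30, 90), y = c(30, 90), t = c(3L, 8L))
  pred <- data.frame(x = c(31, 150), y = c(30, 150), t = c(4L, 9L))
  rep <- evaluate_events(pred, truth, c(20, 200, 200))
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$tpr, 0.5)
  expect_equal(rep$fpr, 0.5)
  expect_equal(rep$mean_spatial_error, 1)
  expect_equal(rep$temporal$mean_abs, 1)
  expect_output(print(rep), "TPR")
})
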