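tiny_cfg <- function() {
  model_config(input_size = 23L, clip_len = 3L, conv_widths = c(2L, 3L),
               conv_dropout = 0, token_dim = 8L, n_heads = 2L,
               n_attention_blocks = 1L, mlp_widths = c(7L), mlp_dropout = 0)
}

test_that("model_config validates and tracks the pooled spatial size", {
  cfg <- model_config()
  expect_equal(cfg$final_spatial, 7L)   # 59 -> 29 -> 14 -> 7
  expect_equal(model_config_compact()$final_spatial, 7L)
  expect_equal(tiny_cfg()$final_spatial, 5L)  # 23 -> 11 -> 5
  expect_error(model_config(token_dim = 10L, n_heads = 3L))
  expect_error(model_config(input_size = 4L,
                            conv_widths = c(2L, 2L, 2L, 2L)), "below 1")
})

test_that("build_model is deterministic per seed and counts parameters", {
  a <- build_model(tiny_cfg(), seed = 4L)
  b <- build_model(tiny_cfg(), seed = 4L)
  expect_identical(a$params, b$params)
  c <- build_model(tiny_cfg(), seed = 5L)
  expect_false(identical(a$params, c$params))
  expect_equal(n_parameters(a),
               sum(vapply(a$params, length, integer(1))))
  expect_output(print(a), "conv_transformer")
})

test_that("forward pass yields calibrated shapes and probabilities", {
  m <- build_model(tiny_cfg(), seed = 1L)
  X <- apodetect:::with_seed(2, array(runif(4 * 3 * 23 * 23, 0, 255),
                                      c(4, 3, 23, 23)))
  fw <- apodetect:::ct_forward(m, X, training = FALSE)
  expect_equal(dim(fw$probs), c(4L, 2L))
  expect_equal(rowSums(fw$probs), rep(1, 4), tolerance = 1e-12)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  # inference is deterministic
  fw2 <- apodetect:::ct_forward(m, X, training = FALSE)
  expect_identical(fw$probs, fw2$probs)
  p <- predict_proba(m, X)
  expect_equal(p, fw$probs[, 2])
  # a single K x S x S clip works too
  p1 <- predict_proba(m, X[1, , , ])
  expect_equal(p1, p[1])
  expect_error(predict_proba(m, array(0, c(2, 3, 10, 10))), "clips must be")
})

test_that("training learns a separable toy problem and returns history", {
  # toy clips: apoptotic = bright centre growing over time
  mk <- function(bright) {
    cl <- array(apodetect:::with_seed(sample.int(1e6, 1),
                                      runif(3 * 23 * 23, 0, 40)), c(3, 23, 23))
    if (bright) for (k in 1:3) cl[k, 9:15, 9:15] <- 120 + 40 * k
    cl
  }
  set.seed(10)
  clips <- lapply(1:40, function(i) mk(i %% 2 == 0))
  lab <- as.integer(seq_len(40) %% 2 == 0)
  cs <- apodetect:::new_clip_set(clips, lab, rep("toy", 40), rep(0L, 40),
                                 rep(0, 40), rep(0, 40))
  tr <- apodetect:::clip_set_subset(cs, 1:32)
  va <- apodetect:::clip_set_subset(cs, 33:40)
  m <- build_model(tiny_cfg(), seed = 2L)
  fit <- train_model(m, tr, va, train_config(lr = 3e-3, batch_size = 8L,
                                             epochs = 12L, seed = 3L))
  expect_s3_class(fit, "conv_transformer")
  expect_true(is.data.frame(fit$history))
  expect_true(all(c("epoch", "loss", "acc", "val_loss", "val_acc", "lr")
                  %in% names(fit$history)))
  expect_gte(max(fit$history$val_acc), 0.9)
  # training is reproducible with the same seed
  fit2 <- train_model(m, tr, va, train_config(lr = 3e-3, batch_size = 8L,
                                              epochs = 12L, seed = 3L))
  expect_identical(fit$params, fit2$params)
})

test_that("model checkpoints round trip through disk", {
  m <- build_model(tiny_cfg(), seed = 6L)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(m, p)
  back <- load_model(p)
  expect_identical(back$params, m$params)
  expect_identical(back$cfg, m$cfg)
  X <- array(runif(2 * 3 * 23 * 23, 0, 255), c(2, 3, 23, 23))
  expect_identical(predict_proba(back, X), predict_proba(m, X))
  # a non-model RDS is rejected
  saveRDS(list(a = 1), p)
  expect_error(load_model(p))
})
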