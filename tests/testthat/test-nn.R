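# Kernel-level checks against naive R oracles and numeric gradients.

test_that("conv kernel matches a naive same-padding 3x3 convolution", {
  set.seed(1)
  H <- 6; W <- 5; N <- 3; Cin <- 2; Cout <- 4
  X <- array(rnorm(H * W * N * Cin), c(H, W, N, Cin))
  Wm <- matrix(rnorm(Cout * 9 * Cin), Cout, 9 * Cin)
  b <- rnorm(Cout)
  fwd <- apodetect:::.nn_conv3_fwd(as.numeric(X), c(H, W, N, Cin), Wm, b, TRUE)
  out <- array(fwd$out, c(H, W, N, Cout))
  naive <- array(0, c(H, W, N, Cout))
  for (n in 1:N) for (co in 1:Cout) for (y in 1:H) for (x in 1:W) {
    s <- b[co]
    for (ci in 1:Cin) for (dx in -1:1) for (dy in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) {
        k <- (dy + 1) + 3 * (dx + 1) + 1
        s <- s + X[yy, xx, n, ci] * Wm[co, k + 9 * (ci - 1)]
      }
    }
    naive[y, x, n, co] <- s
  }
  expect_lt(max(abs(out - naive)), 1e-10)

  # backward pass against central differences
  dout <- array(rnorm(length(out)), dim(out))
  bwd <- apodetect:::.nn_conv3_bwd(as.numeric(dout), c(H, W, N, Cin),
                                   fwd$cols, Wm)
  loss_x <- function(Xv) sum(apodetect:::.nn_conv3_fwd(
    Xv, c(H, W, N, Cin), Wm, b, FALSE)$out * as.numeric(dout))
  ix <- sample(length(X), 12)
  for (i in ix) {
    e <- 1e-5; Xp <- as.numeric(X); Xm <- as.numeric(X)
    Xp[i] <- Xp[i] + e; Xm[i] <- Xm[i] - e
    expect_equal(as.numeric(bwd$dX)[i], (loss_x(Xp) - loss_x(Xm)) / (2 * e),
                 tolerance = 1e-5)
  }
  loss_w <- function(Wv) sum(apodetect:::.nn_conv3_fwd(
    as.numeric(X), c(H, W, N, Cin), matrix(Wv, Cout), b, FALSE)$out *
      as.numeric(dout))
  for (i in sample(length(Wm), 12)) {
    e <- 1e-5; Wp <- as.numeric(Wm); Wn <- as.numeric(Wm)
    Wp[i] <- Wp[i] + e; Wn[i] <- Wn[i] - e
    expect_equal(as.numeric(bwd$dW)[i], (loss_w(Wp) - loss_w(Wn)) / (2 * e),
                 tolerance = 1e-5)
  }
  expect_equal(bwd$db, apply(dout, 4, sum), tolerance = 1e-10)
})

test_that("2x2 max pooling matches the oracle and routes gradients", {
  set.seed(2)
  H <- 7; W <- 6; N <- 2; C <- 3   # odd H exercises the floor semantics
  X <- array(rnorm(H * W * N * C), c(H, W, N, C))
  P <- apodetect:::.nn_maxpool2_fwd(as.numeric(X), c(H, W, N, C))
  Hp <- H %/% 2; Wp <- W %/% 2
  pout <- array(P$out, c(Hp, Wp, N, C))
  for (n in 1:N) for (c in 1:C) for (y in 1:Hp) for (x in 1:Wp)
    expect_equal(pout[y, x, n, c],
                 max(X[(2 * y - 1):(2 * y), (2 * x - 1):(2 * x), n, c]))
  # backward: each upstream gradient lands exactly on its argmax
  dout <- array(rnorm(Hp * Wp * N * C), c(Hp, Wp, N, C))
  dX <- array(apodetect:::.nn_maxpool2_bwd(as.numeric(dout), P$idx,
                                           c(H, W, N, C)), c(H, W, N, C))
  expect_equal(sum(dX != 0), length(dout))
  expect_equal(sum(dX), sum(dout), tolerance = 1e-10)
})

test_that("batch norm forward matches a per-channel R oracle", {
  set.seed(3)
  d <- c(4, 3, 5, 2)
  x <- array(rnorm(prod(d), 2, 3), d)
  gamma <- c(1.5, 0.7); beta <- c(-1, 2)
  stats <- list(mean = c(0, 0), var = c(1, 1))
  f <- apodetect:::bn_forward(x, gamma, beta, stats, training = TRUE)
  for (c in 1:2) {
    xc <- x[, , , c]
    mu <- mean(xc); v <- mean((xc - mu)^2)
    expect_equal(f$out[, , , c], (xc - mu) / sqrt(v + 1e-5) * gamma[c] + beta[c],
                 tolerance = 1e-12)
    # running stats: momentum 0.9, unbiased variance
    m <- length(xc)
    expect_equal(f$stats$mean[c], 0.1 * mu, tolerance = 1e-12)
    expect_equal(f$stats$var[c], 0.9 + 0.1 * v * m / (m - 1), tolerance = 1e-12)
  }
  # inference mode uses the provided running stats
  fi <- apodetect:::bn_forward(x, gamma, beta, list(mean = c(1, 2),
                                                    var = c(4, 9)),
                               training = FALSE)
  expect_equal(fi$out[, , , 1], (x[, , , 1] - 1) / sqrt(4 + 1e-5) * 1.5 - 1,
               tolerance = 1e-12)

  # backward against numeric gradients of sum(out * dout)
  dout <- array(rnorm(prod(d)), d)
  bwd <- apodetect:::bn_backward(dout, gamma, f$cache)
  lf <- function(xv) {
    ff <- apodetect:::bn_forward(array(xv, d), gamma, beta,
                                 list(mean = c(0, 0), var = c(1, 1)), TRUE)
    sum(ff$out * dout)
  }
  for (i in sample(prod(d), 10)) {
    e <- 1e-5; xp <- as.numeric(x); xm <- as.numeric(x)
    xp[i] <- xp[i] + e; xm[i] <- xm[i] - e
    expect_equal(as.numeric(bwd$dx)[i], (lf(xp) - lf(xm)) / (2 * e),
                 tolerance = 1e-4)
  }
})

test_that("layer norm and attention backward match numeric gradients", {
  set.seed(4)
  N <- 6; d <- 8
  x <- matrix(rnorm(N * d), N, d)
  gamma <- runif(d, 0.5, 1.5); beta <- rnorm(d)
  f <- apodetect:::ln_forward(x, gamma, beta)
  dout <- matrix(rnorm(N * d), N, d)
  bwd <- apodetect:::ln_backward(dout, gamma, f$cache)
  lf <- function(xv) sum(apodetect:::ln_forward(matrix(xv, N), gamma,
                                                beta)$out * dout)
  for (i in sample(N * d, 8)) {
    e <- 1e-6; xp <- as.numeric(x); xm <- as.numeric(x)
    xp[i] <- xp[i] + e; xm[i] <- xm[i] - e
    expect_equal(as.numeric(bwd$dx)[i], (lf(xp) - lf(xm)) / (2 * e),
                 tolerance = 1e-4)
  }

  B <- 3; K <- 4; dm <- 8; heads <- 2
  X <- matrix(rnorm(B * K * dm), B * K, dm)
  p <- apodetect:::with_seed(5, list(
    Wq = matrix(rnorm(dm * dm, 0, 0.3), dm), bq = rnorm(dm),
    Wk = matrix(rnorm(dm * dm, 0, 0.3), dm), bk = rnorm(dm),
    Wv = matrix(rnorm(dm * dm, 0, 0.3), dm), bv = rnorm(dm),
    Wo = matrix(rnorm(dm * dm, 0, 0.3), dm), bo = rnorm(dm)))
  fw <- apodetect:::mhsa_forward(X, p, B, K, heads)
  dO <- matrix(rnorm(B * K * dm), B * K, dm)
  bk <- apodetect:::mhsa_backward(dO, p, fw$cache, B, K, heads)
  lX <- function(xv) sum(apodetect:::mhsa_forward(matrix(xv, B * K), p, B, K,
                                                  heads)$out * dO)
  for (i in sample(length(X), 8)) {
    e <- 1e-5; xp <- as.numeric(X); xm <- as.numeric(X)
    xp[i] <- xp[i] + e; xm[i] <- xm[i] - e
    expect_equal(as.numeric(bk$dx)[i], (lX(xp) - lX(xm)) / (2 * e),
                 tolerance = 1e-4)
  }
  lW <- function(wv) {
    p2 <- p; p2$Wq <- matrix(wv, dm)
    sum(apodetect:::mhsa_forward(X, p2, B, K, heads)$out * dO)
  }
  for (i in sample(dm * dm, 6)) {
    e <- 1e-5; wp <- as.numeric(p$Wq); wm <- as.numeric(p$Wq)
    wp[i] <- wp[i] + e; wm[i] <- wm[i] - e
    expect_equal(as.numeric(bk$dWq)[i], (lW(wp) - lW(wm)) / (2 * e),
                 tolerance = 1e-4)
  }
})

test_that("inverted dropout preserves expectation and disables cleanly", {
  x <- matrix(1, 200, 200)
  off <- apodetect:::dropout_forward(x, 0.4, training = FALSE)
  expect_identical(off$out, x)
  expect_null(off$mask)
  on <- apodetect:::with_seed(6, apodetect:::dropout_forward(x, 0.4, TRUE))
  kept <- on$out != 0
  expect_equal(mean(kept), 0.6, tolerance = 0.02)
  expect_true(all(on$out[kept] == 1 / 0.6))
  expect_equal(mean(on$out), 1, tolerance = 0.02)
  d <- apodetect:::dropout_backward(x, on$mask)
  expect_equal(d, x * on$mask)
})

test_that("adam step matches the textbook update", {
  p <- list(w = c(1, 2, 3))
  g <- list(w = c(0.1, -0.2, 0.3))
  st <- apodetect:::adam_init(p)
  up <- apodetect:::adam_step(p, g, st, lr = 0.01)
  m <- 0.1 * g$w; v <- 0.001 * g$w^2
  mh <- m / (1 - 0.9); vh <- v / (1 - 0.999)
  expect_equal(up$params$w, p$w - 0.01 * mh / (sqrt(vh) + 1e-8),
               tolerance = 1e-12)
  expect_equal(up$state$t, 1L)
})

test_that("full-model analytic gradients agree with numeric gradients", {
  cfg <- model_config(input_size = 23L, clip_len = 3L,
                      conv_widths = c(2L, 3L), conv_dropout = 0,
                      token_dim = 8L, n_heads = 2L, n_attention_blocks = 1L,
                      mlp_widths = c(7L), mlp_dropout = 0)
  m <- build_model(cfg, seed = 3)
  set.seed(7)
  B <- 3
  Xc <- array(runif(B * 3 * 23 * 23, 0, 255), c(B, 3, 23, 23))
  y <- c(0L, 1L, 1L)
  fw <- apodetect:::ct_forward(m, Xc, training = TRUE)
  lg <- apodetect:::ct_loss_grads(fw$model, fw, y)
  worst <- 0
  for (pn in names(m$params)) {
    np <- length(m$params[[pn]])
    for (i in sample(np, min(2, np))) {
      e <- 1e-4
      up <- fw$model; up$params[[pn]][i] <- up$params[[pn]][i] + e
      dn <- fw$model; dn$params[[pn]][i] <- dn$params[[pn]][i] - e
      lp <- apodetect:::ct_loss_grads(up, apodetect:::ct_forward(up, Xc, TRUE), y)$loss
      lm <- apodetect:::ct_loss_grads(dn, apodetect:::ct_forward(dn, Xc, TRUE), y)$loss
      g_num <- (lp - lm) / (2 * e)
      g_an <- lg$grads[[pn]][i]
      # scale-aware: conv biases are cancelled by the following batch norm,
      # so both gradients are ~0 and the comparison is noise-dominated there
      err <- abs(g_num - g_an) / max(1e-2, abs(g_num) + abs(g_an))
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 5e-3)
})
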