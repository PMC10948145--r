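# Neural-network primitives for the Conv-Transformer sequence classifier.
#
# The classifier is small enough that explicit forward/backward passes over
# named parameter lists (with im2col convolutions backed by C++ kernels and
# BLAS matrix products) are both transparent and fast; no external deep
# learning framework is used. Feature maps use the (H, W, N, C) layout shared
# with src/nn_ops.cpp, where N = batch * frames and sample index
# n = b + B * (k - 1) (batch fastest), so tokens reshape to (B, K, d) without
# copies.

relu <- function(x) pmax(x, 0)

# ---- batch normalization (per channel, layout (H, W, N, C)) ---------------

bn_forward <- function(x, gamma, beta, stats, training, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  m <- prod(d[1:3])
  if (training) {
    mv <- .nn_col_meanvar(x, m, C)
    mu <- mv$mean
    var <- mv$var
    stats$mean <- momentum * stats$mean + (1 - momentum) * mu
    stats$var <- momentum * stats$var + (1 - momentum) * var * m / max(1, m - 1)
  } else {
    mu <- stats$mean
    var <- stats$var
  }
  inv <- 1 / sqrt(var + eps)
  ap <- .nn_bn_apply(x, m, C, mu, inv, gamma, beta)
  out <- ap$out
  dim(out) <- d
  list(out = out, cache = list(xhat = ap$xhat, inv = inv, dims = d),
       stats = stats)
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims
  m <- prod(d[1:3])
  bw <- .nn_bn_bwd(dout, cache$xhat, m, d[4], gamma, cache$inv)
  dx <- bw$dx
  dim(dx) <- d
  list(dx = dx, dgamma = bw$dgamma, dbeta = bw$dbeta)
}

# ---- layer normalization (rows of an N x d matrix) ------------------------

ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, gamma, `*`) + matrix(beta, nrow(x), length(beta),
                                                 byrow = TRUE),
       cache = list(xhat = xhat, inv = inv))
}

ln_backward <- function(dout, gamma, cache) {
  d <- ncol(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, `*`)
  dx <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout (inverted) ---------------------------------------------------

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- (array(runif(length(x)), dim(x) %||% length(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# ---- multi-head self-attention over K tokens ------------------------------
# X: (N x d) with n = b + B*(k-1); returns same shape.

mhsa_forward <- function(X, p, B, K, n_heads) {
  d <- ncol(X)
  dh <- d %/% n_heads
  Q <- X %*% p$Wq; Q <- sweep(Q, 2, p$bq, `+`)
  Km <- X %*% p$Wk; Km <- sweep(Km, 2, p$bk, `+`)
  V <- X %*% p$Wv; V <- sweep(V, 2, p$bv, `+`)
  rows <- lapply(seq_len(K), function(k) (k - 1L) * B + seq_len(B))
  O <- matrix(0, nrow(X), d)
  A_all <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- Km[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    S <- array(0, c(B, K, K))
    for (i in seq_len(K)) for (j in seq_len(K))
      S[, i, j] <- rowSums(Qh[rows[[i]], , drop = FALSE] *
                             Kh[rows[[j]], , drop = FALSE]) / sqrt(dh)
    # softmax over j
    S <- S - array(apply(S, c(1, 2), max), c(B, K, K))
    E <- exp(S)
    A <- E / array(apply(E, c(1, 2), sum), c(B, K, K))
    for (i in seq_len(K)) {
      acc <- matrix(0, B, dh)
      for (j in seq_len(K))
        acc <- acc + A[, i, j] * Vh[rows[[j]], , drop = FALSE]
      O[rows[[i]], cols] <- acc
    }
    A_all[[h]] <- A
  }
  out <- O %*% p$Wo
  out <- sweep(out, 2, p$bo, `+`)
  list(out = out, cache = list(X = X, Q = Q, K = Km, V = V, O = O,
                               A = A_all, rows = rows, dh = dh))
}

mhsa_backward <- function(dout, p, cache, B, K, n_heads) {
  dh <- cache$dh
  rows <- cache$rows
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, nrow(dout), ncol(dout))
  dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- cache$Q[, cols, drop = FALSE]
    Kh <- cache$K[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    A <- cache$A[[h]]
    dA <- array(0, c(B, K, K))
    for (i in seq_len(K)) for (j in seq_len(K)) {
      dA[, i, j] <- rowSums(dOh[rows[[i]], , drop = FALSE] *
                              Vh[rows[[j]], , drop = FALSE])
      dV[rows[[j]], cols] <- dV[rows[[j]], cols] +
        A[, i, j] * dOh[rows[[i]], , drop = FALSE]
    }
    # softmax backward over j
    s <- array(apply(A * dA, c(1, 2), sum), c(B, K, K))
    dS <- A * (dA - s)
    for (i in seq_len(K)) for (j in seq_len(K)) {
      dQ[rows[[i]], cols] <- dQ[rows[[i]], cols] +
        dS[, i, j] * Kh[rows[[j]], , drop = FALSE] / sqrt(dh)
      dK[rows[[j]], cols] <- dK[rows[[j]], cols] +
        dS[, i, j] * Qh[rows[[i]], , drop = FALSE] / sqrt(dh)
    }
  }
  X <- cache$X
  list(dx = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = crossprod(X, dQ), dbq = colSums(dQ),
       dWk = crossprod(X, dK), dbk = colSums(dK),
       dWv = crossprod(X, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

# ---- parameter initialization --------------------------------------------

he_mat <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                     nin, nout)

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
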