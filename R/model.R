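#' Conv-Transformer model configuration
#'
#' Architecture of the sequence classifier: a time-distributed convolutional
#' feature extractor (three conv blocks, each 3x3 convolution with
#' size-preserving padding, ReLU, batch normalization, dropout and 2x2 max
#' pooling, applied identically to each of the K input frames), a linear
#' projection of the per-frame features to `token_dim`-dimensional tokens
#' with learned positional embeddings, `n_attention_blocks` transformer
#' blocks (multi-head self-attention and feed-forward sublayers, residual
#' connections, post-norm), mean pooling over tokens and a fully connected
#' decision head ending in a 2-way softmax.
#'
#' Defaults follow the published architecture (conv widths 64/128/256, six
#' attention heads, MLP 1024/512/128/64, dropout 0.3, K = 5 frames of
#' 59x59 pixels). [model_config_compact()] is a narrow preset of the same
#' architecture for CPU-scale training runs.
#'
#' @param input_size spatial input size in pixels.
#' @param clip_len K, number of input frames.
#' @param conv_widths channel widths of the three conv blocks.
#' @param conv_dropout dropout rate inside conv blocks.
#' @param token_dim token width after the per-frame projection (must be a
#'   multiple of `n_heads`; the default 240 is the nearest multiple of six
#'   heads to the conv output width).
#' @param n_heads attention heads (must divide `token_dim`).
#' @param n_attention_blocks number of transformer blocks.
#' @param ffn_mult feed-forward width as a multiple of `token_dim`.
#' @param mlp_widths widths of the fully connected decision layers.
#' @param mlp_dropout dropout rate in the decision head.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_size = 59L, clip_len = 5L,
                         conv_widths = c(64L, 128L, 256L),
                         conv_dropout = 0.3, token_dim = 240L, n_heads = 6L,
                         n_attention_blocks = 4L, ffn_mult = 2L,
                         mlp_widths = c(1024L, 512L, 128L, 64L),
                         mlp_dropout = 0.3) {
  stopifnot(token_dim %% n_heads == 0L, all(conv_widths > 0),
            conv_dropout >= 0, conv_dropout < 1, mlp_dropout >= 0,
            mlp_dropout < 1, n_attention_blocks >= 1L)
  sp <- input_size
  for (i in seq_along(conv_widths)) {
    sp <- sp %/% 2L
    if (sp < 1L) stop("pooling reduces spatial size below 1")
  }
  structure(list(input_size = as.integer(input_size),
                 clip_len = as.integer(clip_len),
                 conv_widths = as.integer(conv_widths),
                 conv_dropout = conv_dropout,
                 token_dim = as.integer(token_dim),
                 n_heads = as.integer(n_heads),
                 n_attention_blocks = as.integer(n_attention_blocks),
                 ffn_mult = as.integer(ffn_mult),
                 mlp_widths = as.integer(mlp_widths),
                 mlp_dropout = mlp_dropout,
                 final_spatial = as.integer(sp)),
            class = "model_config")
}

#' @rdname model_config
#' @export
model_config_compact <- function() {
  model_config(conv_widths = c(8L, 16L, 32L), conv_dropout = 0.1,
               token_dim = 48L, n_heads = 2L, n_attention_blocks = 2L,
               mlp_widths = c(64L, 32L), mlp_dropout = 0.1)
}

#' Build an untrained Conv-Transformer classifier
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return A list of class `conv_transformer` (parameters, batch-norm
#'   statistics and configuration).
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_along(cfg$conv_widths)) {
      cout <- cfg$conv_widths[l]
      p[[paste0("conv", l, "_W")]] <- matrix(
        rnorm(cout * 9L * cin, 0, sqrt(2 / (9 * cin))), cout, 9L * cin)
      p[[paste0("conv", l, "_b")]] <- numeric(cout)
      p[[paste0("bn", l, "_g")]] <- rep(1, cout)
      p[[paste0("bn", l, "_b")]] <- numeric(cout)
      cin <- cout
    }
    flat <- cfg$final_spatial^2 * cin
    d <- cfg$token_dim
    p$proj_W <- he_mat(flat, d)
    p$proj_b <- numeric(d)
    # positional scale matters: the clip representation is mean-pooled over
    # tokens, so frame order reaches the head only through nonlinear
    # content-position interactions; embeddings must start at the same order
    # of magnitude as the content tokens for that pathway to carry gradient
    p$pos <- matrix(rnorm(cfg$clip_len * d, 0, 0.5), cfg$clip_len, d)
    for (j in seq_len(cfg$n_attention_blocks)) {
      pre <- paste0("att", j, "_")
      sc <- sqrt(1 / d)
      for (nm in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(pre, nm)]] <- matrix(rnorm(d * d, 0, sc), d, d)
      for (nm in c("bq", "bk", "bv", "bo"))
        p[[paste0(pre, nm)]] <- numeric(d)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- numeric(d)
      dff <- cfg$ffn_mult * d
      p[[paste0(pre, "ffn_W1")]] <- he_mat(d, dff)
      p[[paste0(pre, "ffn_b1")]] <- numeric(dff)
      p[[paste0(pre, "ffn_W2")]] <- matrix(rnorm(dff * d, 0, sqrt(1 / dff)),
                                           dff, d)
      p[[paste0(pre, "ffn_b2")]] <- numeric(d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- numeric(d)
    }
    nin <- d
    for (i in seq_along(cfg$mlp_widths)) {
      p[[paste0("mlp", i, "_W")]] <- he_mat(nin, cfg$mlp_widths[i])
      p[[paste0("mlp", i, "_b")]] <- numeric(cfg$mlp_widths[i])
      nin <- cfg$mlp_widths[i]
    }
    p$out_W <- matrix(rnorm(nin * 2L, 0, sqrt(1 / nin)), nin, 2L)
    p$out_b <- numeric(2L)
    stats <- lapply(seq_along(cfg$conv_widths), function(l)
      list(mean = numeric(cfg$conv_widths[l]),
           var = rep(1, cfg$conv_widths[l])))
    structure(list(cfg = cfg, params = p, bn_stats = stats),
              class = "conv_transformer")
  })
}

#' Number of trainable parameters
#' @param model a `conv_transformer`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.conv_transformer <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("conv_transformer: %d frames x %dx%d, conv %s, ",
                     "%d blocks x %d heads (d=%d), mlp %s, %s parameters\n"),
              cfg$clip_len, cfg$input_size, cfg$input_size,
              paste(cfg$conv_widths, collapse = "/"),
              cfg$n_attention_blocks, cfg$n_heads, cfg$token_dim,
              paste(cfg$mlp_widths, collapse = "/"),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# forward / backward

# X: array (B, K, S, S) on the 8-bit scale. Returns class probabilities and,
# when training, all caches needed for the backward pass. Dropout draws come
# from the current RNG stream.
ct_forward <- function(model, X, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(X)
  B <- d[1]; K <- d[2]; S <- d[3]
  x <- aperm(X, c(3, 4, 1, 2)) / 255
  dim(x) <- c(S, S, B * K, 1L)
  caches <- list()
  for (l in seq_along(cfg$conv_widths)) {
    din <- dim(x)
    cv <- .nn_conv3_fwd(x, din, p[[paste0("conv", l, "_W")]],
                        p[[paste0("conv", l, "_b")]], training)
    a <- cv$out
    rmask <- a > 0
    a <- a * rmask
    bn <- bn_forward(a, p[[paste0("bn", l, "_g")]],
                     p[[paste0("bn", l, "_b")]], model$bn_stats[[l]],
                     training)
    model$bn_stats[[l]] <- bn$stats
    dr <- dropout_forward(bn$out, cfg$conv_dropout, training)
    mp <- .nn_maxpool2_fwd(dr$out, dim(dr$out))
    caches[[l]] <- list(din = din, cols = cv$cols, rmask = rmask,
                        bn = bn$cache, mask = dr$mask, idx = mp$idx,
                        pdim = dim(dr$out))
    x <- mp$out
  }
  fd <- dim(x)
  feat <- aperm(x, c(1, 2, 4, 3))
  dim(feat) <- c(prod(fd[c(1, 2, 4)]), fd[3])
  feat <- t(feat)                                   # N x flat
  tok <- sweep(feat %*% p$proj_W, 2, p$proj_b, `+`) # N x d
  posmat <- p$pos[rep(seq_len(K), each = B), , drop = FALSE]
  tok <- tok + posmat
  att_caches <- list()
  for (j in seq_len(cfg$n_attention_blocks)) {
    pre <- paste0("att", j, "_")
    ap <- list(Wq = p[[paste0(pre, "Wq")]], bq = p[[paste0(pre, "bq")]],
               Wk = p[[paste0(pre, "Wk")]], bk = p[[paste0(pre, "bk")]],
               Wv = p[[paste0(pre, "Wv")]], bv = p[[paste0(pre, "bv")]],
               Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]])
    at <- mhsa_forward(tok, ap, B, K, cfg$n_heads)
    r1 <- tok + at$out
    l1 <- ln_forward(r1, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    h_pre <- sweep(l1$out %*% p[[paste0(pre, "ffn_W1")]], 2,
                   p[[paste0(pre, "ffn_b1")]], `+`)
    hmask <- h_pre > 0
    h <- h_pre * hmask
    hdr <- dropout_forward(h, cfg$mlp_dropout, training)
    f <- sweep(hdr$out %*% p[[paste0(pre, "ffn_W2")]], 2,
               p[[paste0(pre, "ffn_b2")]], `+`)
    r2 <- l1$out + f
    l2 <- ln_forward(r2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    att_caches[[j]] <- list(tok_in = tok, at = at$cache, l1 = l1$cache,
                            l1_out = l1$out, hmask = hmask, hdrop = hdr$mask,
                            hout = hdr$out, l2 = l2$cache)
    tok <- l2$out
  }
  rows <- lapply(seq_len(K), function(k) (k - 1L) * B + seq_len(B))
  pool <- Reduce(`+`, lapply(rows, function(r) tok[r, , drop = FALSE])) / K
  mlp_caches <- list()
  h <- pool
  for (i in seq_along(cfg$mlp_widths)) {
    z <- sweep(h %*% p[[paste0("mlp", i, "_W")]], 2,
               p[[paste0("mlp", i, "_b")]], `+`)
    zmask <- z > 0
    z <- z * zmask
    dr <- dropout_forward(z, cfg$mlp_dropout, training)
    mlp_caches[[i]] <- list(hin = h, zmask = zmask, mask = dr$mask,
                            out = dr$out)
    h <- dr$out
  }
  logits <- sweep(h %*% p$out_W, 2, p$out_b, `+`)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, model = model,
       cache = if (training) list(conv = caches, fd = fd, feat = feat,
                                  att = att_caches, tok = tok, rows = rows,
                                  pool = pool, mlp = mlp_caches,
                                  mlp_in = h, B = B, K = K) else NULL)
}

# Cross-entropy loss and full gradient. y: 0/1 labels.
ct_loss_grads <- function(model, fwd, y) {
  cfg <- model$cfg
  p <- model$params
  cc <- fwd$cache
  B <- cc$B; K <- cc$K
  probs <- fwd$probs
  Y <- cbind(1 - y, y)
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), y + 1L)], 1e-12)))
  g <- list()
  dlog <- (probs - Y) / B
  g$out_W <- crossprod(cc$mlp_in, dlog)
  g$out_b <- colSums(dlog)
  dh <- dlog %*% t(p$out_W)
  for (i in rev(seq_along(cfg$mlp_widths))) {
    mc <- cc$mlp[[i]]
    dz <- dropout_backward(dh, mc$mask) * mc$zmask
    g[[paste0("mlp", i, "_W")]] <- crossprod(mc$hin, dz)
    g[[paste0("mlp", i, "_b")]] <- colSums(dz)
    dh <- dz %*% t(p[[paste0("mlp", i, "_W")]])
  }
  dtok <- matrix(0, B * K, cfg$token_dim)
  for (r in cc$rows) dtok[r, ] <- dh / K
  for (j in rev(seq_len(cfg$n_attention_blocks))) {
    pre <- paste0("att", j, "_")
    ac <- cc$att[[j]]
    l2b <- ln_backward(dtok, p[[paste0(pre, "ln2_g")]], ac$l2)
    g[[paste0(pre, "ln2_g")]] <- l2b$dgamma
    g[[paste0(pre, "ln2_b")]] <- l2b$dbeta
    dr2 <- l2b$dx
    g[[paste0(pre, "ffn_W2")]] <- crossprod(ac$hout, dr2)
    g[[paste0(pre, "ffn_b2")]] <- colSums(dr2)
    dhh <- dropout_backward(dr2 %*% t(p[[paste0(pre, "ffn_W2")]]),
                            ac$hdrop) * ac$hmask
    g[[paste0(pre, "ffn_W1")]] <- crossprod(ac$l1_out, dhh)
    g[[paste0(pre, "ffn_b1")]] <- colSums(dhh)
    dl1 <- dr2 + dhh %*% t(p[[paste0(pre, "ffn_W1")]])
    l1b <- ln_backward(dl1, p[[paste0(pre, "ln1_g")]], ac$l1)
    g[[paste0(pre, "ln1_g")]] <- l1b$dgamma
    g[[paste0(pre, "ln1_b")]] <- l1b$dbeta
    dr1 <- l1b$dx
    ap <- list(Wq = p[[paste0(pre, "Wq")]], Wk = p[[paste0(pre, "Wk")]],
               Wv = p[[paste0(pre, "Wv")]], Wo = p[[paste0(pre, "Wo")]])
    ab <- mhsa_backward(dr1, ap, ac$at, B, K, cfg$n_heads)
    for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))
      g[[paste0(pre, nm)]] <- ab[[paste0("d", nm)]]
    dtok <- dr1 + ab$dx
  }
  g$pos <- t(vapply(seq_len(K), function(k)
    colSums(dtok[cc$rows[[k]], , drop = FALSE]), numeric(cfg$token_dim)))
  g$proj_W <- crossprod(cc$feat, dtok)
  g$proj_b <- colSums(dtok)
  dfeat <- dtok %*% t(p$proj_W)            # N x flat
  fd <- cc$fd
  dx <- t(dfeat)
  dim(dx) <- c(fd[1], fd[2], fd[4], fd[3])
  dx <- aperm(dx, c(1, 2, 4, 3))
  for (l in rev(seq_along(cfg$conv_widths))) {
    lc <- cc$conv[[l]]
    dpool <- .nn_maxpool2_bwd(dx, lc$idx, lc$pdim)
    ddr <- dropout_backward(dpool, lc$mask)
    bnb <- bn_backward(ddr, p[[paste0("bn", l, "_g")]], lc$bn)
    g[[paste0("bn", l, "_g")]] <- bnb$dgamma
    g[[paste0("bn", l, "_b")]] <- bnb$dbeta
    da <- bnb$dx * lc$rmask
    cb <- .nn_conv3_bwd(da, lc$din, lc$cols, p[[paste0("conv", l, "_W")]])
    g[[paste0("conv", l, "_W")]] <- cb$dW
    g[[paste0("conv", l, "_b")]] <- cb$db
    dx <- cb$dX
  }
  list(loss = loss, grads = g)
}

# ---------------------------------------------------------------------------
# training

#' Training configuration
#'
#' Adam with two-class cross-entropy (the softmax formulation of binary
#' cross-entropy), mini-batches of 32, checkpointing on best validation
#' accuracy, early stopping with patience 15 and learning-rate reduction on a
#' validation-loss plateau.
#'
#' @param lr initial learning rate.
#' @param batch_size mini-batch size.
#' @param epochs maximum training epochs (the published settings are 100 in
#'   vitro and 200 in vivo).
#' @param patience early-stopping patience in epochs.
#' @param lr_factor,lr_patience plateau schedule: multiply `lr` by
#'   `lr_factor` after `lr_patience` epochs without validation-loss
#'   improvement.
#' @param augment optional [loader_config()]; when given, training clips are
#'   re-augmented every epoch.
#' @param seed RNG seed covering shuffling, augmentation and dropout.
#' @param verbose print per-epoch progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 32L, epochs = 100L,
                         patience = 15L, lr_factor = 0.5, lr_patience = 5L,
                         augment = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, patience >= 1L)
  structure(as.list(environment()), class = "train_config")
}

clipset_to_array <- function(cs, k) {
  n <- length(cs$clips)
  s <- dim(cs$clips[[1]])[2]
  X <- array(0, c(n, k, s, s))
  for (i in seq_len(n)) X[i, , , ] <- sample_fixed_length(cs$clips[[i]], k)
  X
}

#' Train the Conv-Transformer
#'
#' @param model an untrained or pre-trained `conv_transformer`.
#' @param train_set,val_set `clip_set`s with disjoint clips (`val_set` drives
#'   checkpointing and early stopping).
#' @param cfg a [train_config()].
#' @return The model checkpoint with the best validation accuracy, with a
#'   `history` data frame (per-epoch training loss/accuracy, validation
#'   loss/accuracy, learning rate) attached.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(model, "conv_transformer"), length(train_set) > 0,
            length(val_set) > 0)
  if (length(unique(train_set$label)) < 2L)
    warning("single-class training set: the loss degenerates")
  K <- model$cfg$clip_len
  Xtr0 <- clipset_to_array(train_set, K)
  ytr <- train_set$label
  Xval <- clipset_to_array(val_set, K)
  yval <- val_set$label
  with_seed(cfg$seed, {
    opt <- adam_init(model$params)
    lr <- cfg$lr
    hist <- list()
    best <- list(acc = -Inf, params = model$params, stats = model$bn_stats)
    stall_acc <- 0L
    stall_loss <- 0L
    best_vloss <- Inf
    n <- dim(Xtr0)[1]
    for (ep in seq_len(cfg$epochs)) {
      Xtr <- Xtr0
      if (!is.null(cfg$augment)) {
        for (i in seq_len(n)) {
          sd_i <- floor(runif(1, 0, 2^31 - 1))
          cl <- augment2d(train_set$clips[[i]], cfg$augment, seed = sd_i)
          Xtr[i, , , ] <- sample_fixed_length(cl, K)
        }
      }
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- Xtr[idx, , , , drop = FALSE]
        yb <- ytr[idx]
        fwd <- ct_forward(model, Xb, training = TRUE)
        model <- fwd$model  # updated bn running stats
        lg <- ct_loss_grads(model, fwd, yb)
        step <- adam_step(model$params, lg$grads, opt, lr)
        model$params <- step$params
        opt <- step$state
        ep_loss <- ep_loss + lg$loss * length(idx)
        ep_correct <- ep_correct +
          sum((fwd$probs[, 2] >= 0.5) == (yb == 1L))
      }
      vp <- ct_predict(model, Xval)
      vloss <- -mean(log(pmax(ifelse(yval == 1L, vp, 1 - vp), 1e-12)))
      vacc <- mean((vp >= 0.5) == (yval == 1L))
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                               acc = ep_correct / n, val_loss = vloss,
                               val_acc = vacc, lr = lr)
      if (cfg$verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                        ep, ep_loss / n, ep_correct / n, vloss, vacc))
      if (vacc > best$acc + 1e-12) {
        best <- list(acc = vacc, params = model$params,
                     stats = model$bn_stats)
        stall_acc <- 0L
      } else stall_acc <- stall_acc + 1L
      if (vloss < best_vloss - 1e-12) {
        best_vloss <- vloss
        stall_loss <- 0L
      } else {
        stall_loss <- stall_loss + 1L
        if (stall_loss >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          stall_loss <- 0L
        }
      }
      if (stall_acc >= cfg$patience) break
    }
    model$params <- best$params
    model$bn_stats <- best$stats
    model$history <- do.call(rbind, hist)
    model
  })
}

# inference forward in chunks; X: (n, K, S, S). Returns P(class 1).
ct_predict <- function(model, X, chunk = 256L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- ct_forward(model, X[idx, , , , drop = FALSE], training = FALSE)
    out[idx] <- fw$probs[, 2]
  }
  out
}

#' Predict apoptosis probabilities for clip sequences
#'
#' @param model a trained `conv_transformer`.
#' @param clips a `clip_set`, an array `n x K x S x S`, or a single clip
#'   `K x S x S` (8-bit values; scaled internally).
#' @return Numeric vector of P(apoptotic) in \[0, 1\].
#' @export
predict_proba <- function(model, clips) {
  K <- model$cfg$clip_len
  X <- if (inherits(clips, "clip_set")) {
    clipset_to_array(clips, K)
  } else if (length(dim(clips)) == 3L) {
    cl <- sample_fixed_length(clips, K)
    array(cl, c(1L, dim(cl)))
  } else clips
  if (length(dim(X)) != 4L || dim(X)[2] != K ||
      dim(X)[3] != model$cfg$input_size || dim(X)[4] != model$cfg$input_size)
    stop("clips must be n x ", K, " x ", model$cfg$input_size, " x ",
         model$cfg$input_size)
  ct_predict(model, X)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture configuration, parameters,
#' batch-norm statistics and training history in a single file.
#'
#' @param model a `conv_transformer`.
#' @param path checkpoint path.
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "conv_transformer"))
  model
}
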