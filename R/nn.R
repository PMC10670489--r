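# Internal neural-network engine for the windowed CNN-LSTM classifier.
#
# The network processes each spectrum as k_s equal-length slices. A shared
# ("time-distributed") 1-D convolutional stack extracts features from every
# slice; the flattened per-slice features form a length-k_s sequence consumed
# by an LSTM; a dense softmax head classifies, and an optional selective
# branch emits a confidence score used by the reject option. Convolutions are
# evaluated as im2col matrix products so all heavy lifting is BLAS; gradients
# are derived manually and optimized with Adam.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Architecture constants for the two depth variants. Strides do the
# downsampling; kernel length is the configured kernel width (default 4).
cnn_arch <- function(cfg) {
  k <- cfg$kernel_width
  if (cfg$n_layers == 25) {
    list(conv = list(list(f = 64, k = k, s = 4),
                     list(f = 128, k = k, s = 4),
                     list(f = 256, k = k, s = 4)),
         head_hidden = 0L)
  } else {
    list(conv = list(list(f = 64, k = k, s = 2),
                     list(f = 64, k = k, s = 2),
                     list(f = 128, k = k, s = 2),
                     list(f = 128, k = k, s = 2),
                     list(f = 256, k = k, s = 2),
                     list(f = 256, k = k, s = 1),
                     list(f = 256, k = k, s = 1)),
         head_hidden = 64L)
  }
}

conv_out_len <- function(L, k, s) {
  if (L < k) stop(sprintf("slice too short for the convolution stack (need >= %d points)", k))
  (L - k) %/% s + 1L
}

# Per-layer output lengths and the flattened feature dimension.
conv_dims <- function(arch, slice_len) {
  L <- slice_len
  lens <- integer(length(arch$conv))
  for (i in seq_along(arch$conv)) {
    L <- conv_out_len(L, arch$conv[[i]]$k, arch$conv[[i]]$s)
    lens[i] <- L
  }
  list(lens = lens, feat_dim = L * arch$conv[[length(arch$conv)]]$f)
}

nn_init <- function(cfg, slice_len) {
  arch <- cnn_arch(cfg)
  dims <- conv_dims(arch, slice_len)
  H <- cfg$lstm_units
  p <- list()
  cin <- 1L
  for (i in seq_along(arch$conv)) {
    f <- arch$conv[[i]]$f; k <- arch$conv[[i]]$k
    p[[paste0("conv", i, "_W")]] <-
      matrix(stats::rnorm(k * cin * f, sd = sqrt(2 / (k * cin))), k * cin, f)
    p[[paste0("conv", i, "_b")]] <- numeric(f)
    cin <- f
  }
  D <- dims$feat_dim
  p$lstm_Wx <- matrix(stats::rnorm(D * 4 * H, sd = sqrt(1 / D)), D, 4 * H)
  p$lstm_Wh <- matrix(stats::rnorm(H * 4 * H, sd = sqrt(1 / H)), H, 4 * H)
  p$lstm_b <- numeric(4 * H)
  p$lstm_b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  if (arch$head_hidden > 0) {
    hh <- arch$head_hidden
    p$head_W1 <- matrix(stats::rnorm(H * hh, sd = sqrt(2 / H)), H, hh)
    p$head_b1 <- numeric(hh)
    p$head_W2 <- matrix(stats::rnorm(hh * 2, sd = sqrt(2 / hh)), hh, 2)
    p$head_b2 <- numeric(2)
  } else {
    p$head_W2 <- matrix(stats::rnorm(H * 2, sd = sqrt(2 / H)), H, 2)
    p$head_b2 <- numeric(2)
  }
  if (isTRUE(cfg$selective)) {
    p$sel_V1 <- matrix(stats::rnorm(H * 32, sd = sqrt(2 / H)), H, 32)
    p$sel_c1 <- numeric(32)
    p$sel_V2 <- matrix(stats::rnorm(32, sd = sqrt(2 / 32)), 32, 1)
    p$sel_c2 <- 0
  }
  p
}

# im2col 1-D convolution + ReLU. A3: [m, L, C]. Returns activations and the
# quantities needed for the backward pass.
conv_fwd <- function(A3, W, b, k, s) {
  m <- dim(A3)[1]; L <- dim(A3)[2]; C <- dim(A3)[3]
  Lout <- (L - k) %/% s + 1L
  starts <- (seq_len(Lout) - 1L) * s
  idx <- as.vector(outer(seq_len(k), starts, `+`))
  Asub <- A3[, idx, , drop = FALSE]
  dim(Asub) <- c(m, k, Lout, C)
  M <- aperm(Asub, c(1, 3, 2, 4))
  dim(M) <- c(m * Lout, k * C)
  Z <- M %*% W
  Z <- Z + rep(b, each = nrow(Z))
  mask <- Z > 0
  Z[!mask] <- 0
  out <- Z
  dim(out) <- c(m, Lout, ncol(W))
  list(out = out, M = M, mask = mask, Lout = Lout, starts = starts,
       in_dim = c(m, L, C), k = k)
}

conv_bwd <- function(cache, W, dOut3) {
  m <- cache$in_dim[1]
  dZ <- dOut3
  dim(dZ) <- c(m * cache$Lout, ncol(W))
  dZ <- dZ * cache$mask
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, W)
  k <- cache$k; C <- cache$in_dim[3]
  dim(dM) <- c(m, cache$Lout, k, C)
  dA <- array(0, cache$in_dim)
  for (j in seq_len(k)) {
    pos <- cache$starts + j
    dA[, pos, ] <- dA[, pos, ] + dM[, , j, ]
  }
  list(dA = dA, dW = dW, db = db)
}

lstm_fwd <- function(SEQ, Wx, Wh, bias) {
  b <- dim(SEQ)[1]; ks <- dim(SEQ)[2]
  H <- nrow(Wh)
  h <- matrix(0, b, H); cs <- matrix(0, b, H)
  caches <- vector("list", ks)
  for (t in seq_len(ks)) {
    Xt <- SEQ[, t, , drop = FALSE]; dim(Xt) <- c(b, dim(SEQ)[3])
    zb <- Xt %*% Wx + h %*% Wh
    zb <- zb + rep(bias, each = b)
    i <- sigmoid(zb[, 1:H, drop = FALSE])
    f <- sigmoid(zb[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(zb[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(zb[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cs + i * g
    h_new <- o * tanh(c_new)
    caches[[t]] <- list(Xt = Xt, h_prev = h, c_prev = cs, i = i, f = f,
                        o = o, g = g, c_new = c_new)
    h <- h_new; cs <- c_new
  }
  list(h = h, caches = caches)
}

lstm_bwd <- function(fw, Wx, Wh, dh_top) {
  ks <- length(fw$caches)
  H <- nrow(Wh); b <- nrow(dh_top); D <- nrow(Wx)
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dSEQ <- array(0, c(b, ks, D))
  dh <- dh_top; dc <- matrix(0, b, H)
  for (t in rev(seq_len(ks))) {
    cc <- fw$caches[[t]]
    tc <- tanh(cc$c_new)
    do <- dh * tc
    dc <- dc + dh * cc$o * (1 - tc^2)
    di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
    dzb <- cbind(di * cc$i * (1 - cc$i),
                 df * cc$f * (1 - cc$f),
                 do * cc$o * (1 - cc$o),
                 dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$Xt, dzb)
    dWh <- dWh + crossprod(cc$h_prev, dzb)
    db <- db + colSums(dzb)
    dSEQ[, t, ] <- dzb %*% t(Wx)
    dh <- dzb %*% t(Wh)
    dc <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dSEQ = dSEQ)
}

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) > p) / (1 - p), nr, nc)
}

# Forward pass (and, when `y` is given, backward pass) through the whole
# network. X3: [b, ks, L]; y: integer class index (1 = negative, 2 =
# positive) or NULL for inference.
nn_pass <- function(params, X3, y, cfg, train = FALSE) {
  arch <- cnn_arch(cfg)
  b <- dim(X3)[1]; ks <- dim(X3)[2]; L <- dim(X3)[3]
  m <- b * ks
  A3 <- X3
  dim(A3) <- c(m, L)      # rows: spectrum index fastest, then slice
  A3 <- array(A3, c(m, L, 1L))
  caches <- vector("list", length(arch$conv))
  for (i in seq_along(arch$conv)) {
    cv <- arch$conv[[i]]
    caches[[i]] <- conv_fwd(A3, params[[paste0("conv", i, "_W")]],
                            params[[paste0("conv", i, "_b")]], cv$k, cv$s)
    A3 <- caches[[i]]$out
  }
  feat <- A3
  D <- dim(feat)[2] * dim(feat)[3]
  dim(feat) <- c(m, D)
  fmask <- if (train) dropout_mask(m, D, cfg$dropout) else NULL
  if (!is.null(fmask)) feat <- feat * fmask
  SEQ <- feat
  dim(SEQ) <- c(b, ks, D)
  lf <- lstm_fwd(SEQ, params$lstm_Wx, params$lstm_Wh, params$lstm_b)
  h <- lf$h
  hmask <- if (train) dropout_mask(b, ncol(h), cfg$head_dropout) else NULL
  hd <- if (is.null(hmask)) h else h * hmask
  if (arch$head_hidden > 0) {
    z1 <- hd %*% params$head_W1 + rep(params$head_b1, each = b)
    m1 <- z1 > 0; a1 <- z1 * m1
    logits <- a1 %*% params$head_W2 + rep(params$head_b2, each = b)
  } else {
    logits <- hd %*% params$head_W2 + rep(params$head_b2, each = b)
  }
  logits <- logits - apply(logits, 1, max)
  expz <- exp(logits)
  probs <- expz / rowSums(expz)
  conf <- NULL
  if (isTRUE(cfg$selective)) {
    zs <- h %*% params$sel_V1 + rep(params$sel_c1, each = b)
    ms <- zs > 0; as <- zs * ms
    conf <- drop(sigmoid(as %*% params$sel_V2 + params$sel_c2))
  }
  if (is.null(y)) return(list(probs = probs, conf = conf))

  onehot <- matrix(0, b, 2); onehot[cbind(seq_len(b), y)] <- 1
  ce <- -log(pmax(probs[cbind(seq_len(b), y)], 1e-12))
  if (isTRUE(cfg$selective)) {
    G <- sum(conf); R <- sum(conf * ce)
    cov_gap <- max(0, cfg$target_coverage - mean(conf))
    loss <- R / G + cfg$lambda * cov_gap^2 + 0.5 * mean(ce)
    dce <- conf / G + 0.5 / b
    dconf <- (ce * G - R) / G^2 - 2 * cfg$lambda * cov_gap / b
  } else {
    loss <- mean(ce)
    dce <- rep(1 / b, b)
    dconf <- NULL
  }
  grads <- list()
  dlogits <- (probs - onehot) * dce
  if (arch$head_hidden > 0) {
    grads$head_W2 <- crossprod(a1, dlogits)
    grads$head_b2 <- colSums(dlogits)
    da1 <- tcrossprod(dlogits, params$head_W2) * m1
    grads$head_W1 <- crossprod(hd, da1)
    grads$head_b1 <- colSums(da1)
    dhd <- tcrossprod(da1, params$head_W1)
  } else {
    grads$head_W2 <- crossprod(hd, dlogits)
    grads$head_b2 <- colSums(dlogits)
    dhd <- tcrossprod(dlogits, params$head_W2)
  }
  dh <- if (is.null(hmask)) dhd else dhd * hmask
  if (isTRUE(cfg$selective)) {
    s <- conf
    dzo <- matrix(dconf * s * (1 - s), b, 1)
    grads$sel_V2 <- crossprod(as, dzo)
    grads$sel_c2 <- sum(dzo)
    das <- tcrossprod(dzo, params$sel_V2) * ms
    grads$sel_V1 <- crossprod(h, das)
    grads$sel_c1 <- colSums(das)
    dh <- dh + tcrossprod(das, params$sel_V1)
  }
  lb <- lstm_bwd(lf, params$lstm_Wx, params$lstm_Wh, dh)
  grads$lstm_Wx <- lb$dWx; grads$lstm_Wh <- lb$dWh; grads$lstm_b <- lb$db
  dfeat <- lb$dSEQ
  dim(dfeat) <- c(m, D)
  if (!is.null(fmask)) dfeat <- dfeat * fmask
  dA3 <- dfeat
  dim(dA3) <- c(m, dim(caches[[length(caches)]]$out)[2],
                dim(caches[[length(caches)]]$out)[3])
  for (i in rev(seq_along(arch$conv))) {
    cb <- conv_bwd(caches[[i]], params[[paste0("conv", i, "_W")]], dA3)
    grads[[paste0("conv", i, "_W")]] <- cb$dW
    grads[[paste0("conv", i, "_b")]] <- cb$db
    dA3 <- cb$dA
  }
  list(loss = loss, grads = grads, probs = probs, conf = conf)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# Mini-batch training loop with optional on-the-fly augmentation of the
# training windows and early stopping on validation loss.
nn_fit <- function(params, X3, y, cfg, Xval = NULL, yval = NULL,
                   aug_fun = NULL, verbose = FALSE) {
  st <- adam_init(params)
  n <- dim(X3)[1]
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    Xep <- if (is.null(aug_fun)) X3 else aug_fun(X3)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      pass <- nn_pass(params, Xep[idx, , , drop = FALSE], y[idx], cfg,
                      train = TRUE)
      upd <- adam_step(params, pass$grads, st, cfg$learning_rate)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + pass$loss; nb <- nb + 1L
    }
    vl <- NA_real_
    if (!is.null(Xval)) {
      vp <- nn_pass(params, Xval, yval, cfg, train = FALSE)
      vl <- vp$loss
      if (vl < best$loss - 1e-5) {
        best <- list(loss = vl, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          hist <- rbind(hist, data.frame(epoch = ep,
                                         train_loss = ep_loss / nb,
                                         val_loss = vl))
          break
        }
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, ep_loss / nb, vl))
  }
  if (!is.null(Xval) && best$epoch > 0) params <- best$params
  list(params = params, history = hist)
}
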