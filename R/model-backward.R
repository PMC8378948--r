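# Backpropagation through the CRNN. Gradient containers mirror the
# parameter containers; every formula is the analytic derivative of the
# corresponding forward stage and is checked against finite differences in
# the test suite.

# Batch-norm backward per channel over the rows of the flattened map.
bn_backward <- function(dY, cache, gamma) {
  m <- nrow(dY)
  co <- ncol(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * matrix(gamma, m, co, byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- (dxhat - matrix(s1 / m, m, co, byrow = TRUE) -
           cache$xhat * matrix(s2 / m, m, co, byrow = TRUE)) *
    matrix(cache$invstd, m, co, byrow = TRUE)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

conv_block_backward <- function(dout, params, config, cache) {
  dz <- cache$dims
  co <- dz[5]
  dY <- matrix(dout, ncol = co)
  dY[!cache$mask] <- 0
  bn <- bn_backward(dY, cache, params$gamma)
  dpre <- array(bn$dX, dim = dz)
  cv <- conv3d_bwd_cpp(cache$x, params$w, dpre, config$stride)
  list(dx = cv$gx,
       grads = list(w = cv$gw, b = as.numeric(cv$gb),
                    gamma = bn$dgamma, beta = bn$dbeta))
}

lstm_dir_backward <- function(dH, caches, params) {
  B <- dim(dH)[1]
  T_len <- dim(dH)[2]
  Hd <- dim(dH)[3]
  IN <- nrow(params$W) - Hd
  dW <- array(0, dim(params$W))
  db <- numeric(length(params$b))
  dX <- array(0, c(B, T_len, IN))
  dh_next <- matrix(0, B, Hd)
  dc_next <- matrix(0, B, Hd)
  for (t in rev(seq_len(T_len))) {
    ca <- caches[[t]]
    dh <- matrix(dH[, t, ], B, Hd) + dh_next
    do_ <- dh * ca$tanh_c
    dc <- dc_next + dh * ca$o * (1 - ca$tanh_c^2)
    df <- dc * ca$c_prev
    di <- dc * ca$g
    dg <- dc * ca$i
    dc_next <- dc * ca$f
    dZ <- cbind(df * ca$f * (1 - ca$f),
                di * ca$i * (1 - ca$i),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    inp <- cbind(ca$x, ca$h_prev)
    dW <- dW + crossprod(inp, dZ)
    db <- db + colSums(dZ)
    dcomb <- dZ %*% t(params$W)
    dX[, t, ] <- dcomb[, seq_len(IN), drop = FALSE]
    dh_next <- dcomb[, IN + seq_len(Hd), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

attention_backward <- function(dctx, params, cache, type) {
  H3 <- cache$H3
  B <- dim(H3)[1]
  T_len <- dim(H3)[2]
  Fd <- dim(H3)[3]
  dH <- array(0, dim(H3))
  if (type == "additive") {
    W <- cache$W
    ds <- matrix(0, B, T_len)
    for (t in seq_len(T_len)) {
      dH[, t, ] <- W[, t] * dctx
      ds[, t] <- rowSums(dctx * matrix(H3[, t, ], B, Fd))
    }
    dscore <- W * (ds - rowSums(ds * W))
    dsflat <- as.vector(dscore)  # row (t-1)*B + b matches Hflat/U rows
    U <- cache$U
    dU <- (dsflat %o% params$ua) * (1 - U^2)
    dWa <- crossprod(cache$Hflat, dU)
    dba <- colSums(dU)
    dua <- as.numeric(crossprod(U, dsflat))
    dHflat <- dU %*% t(params$Wa)
    dH <- dH + array(dHflat, dim(H3))
    list(dH = dH, grads = list(Wa = dWa, ba = dba, ua = dua))
  } else {
    W3 <- cache$W3
    for (f in seq_len(Fd)) {
      Wf <- matrix(W3[, , f], B, T_len)
      Hf <- matrix(H3[, , f], B, T_len)
      dcf <- dctx[, f]
      # d/dh of sum_t softmax_t(h) * h_t (softmax along time, per feature)
      inner <- Wf * Hf
      dH[, , f] <- dcf * (Wf + Wf * (Hf - rowSums(inner)))
    }
    list(dH = dH, grads = list())
  }
}

# Loss + gradients for one batch. ys are integer labels 0..K-1.
crnn_loss_grads <- function(xs, ys, params, config, training = TRUE) {
  fwd <- crnn_forward(xs, params, config, training = training,
                      keep_cache = TRUE)
  ca <- fwd$cache
  B <- ca$B
  K <- config$n_classes
  Y <- matrix(0, B, K)
  Y[cbind(seq_len(B), ys + 1L)] <- 1
  loss <- cross_entropy(fwd$logits, Y)

  dlogits <- (fwd$probs - Y) / B
  h <- ca$cls$hidden
  dW2 <- crossprod(h, dlogits)
  db2 <- colSums(dlogits)
  dh <- dlogits %*% t(params$dense$W2)
  dh[h <= 0] <- 0
  ctx <- ca$cls$cache$context
  dW1 <- crossprod(ctx, dh)
  db1 <- colSums(dh)
  dctx <- dh %*% t(params$dense$W1)

  att <- attention_backward(dctx, params$att, ca$att$cache,
                            config$attention_type)
  dH <- att$dH
  if (!is.null(ca$bilstm$mask)) dH <- dH * ca$bilstm$mask

  T_len <- ca$T_len
  Hd <- config$lstm_units
  dHf <- dH[, , seq_len(Hd), drop = FALSE]
  dHb <- dH[, , Hd + seq_len(Hd), drop = FALSE]
  fwdg <- lstm_dir_backward(dHf, ca$bilstm$cache$fw, params$lstm$fwd)
  bwdg <- lstm_dir_backward(dHb[, rev(seq_len(T_len)), , drop = FALSE],
                            ca$bilstm$cache$bw, params$lstm$bwd)
  dX3 <- fwdg$dX + bwdg$dX[, rev(seq_len(T_len)), , drop = FALSE]

  feat <- dim(dX3)[3]
  dF <- matrix(dX3, B * T_len, feat)
  last <- length(config$conv_blocks)
  dcur <- array(dF, c(B * T_len, 1L, 1L, 1L, feat))
  conv_grads <- vector("list", last)
  for (i in rev(seq_len(last))) {
    bb <- conv_block_backward(dcur, params$conv[[i]], config$conv_blocks[[i]],
                              ca$cnn$caches[[i]])
    conv_grads[[i]] <- bb$grads
    dcur <- bb$dx
  }

  grads <- list(conv = conv_grads,
                lstm = list(fwd = list(W = fwdg$dW, b = fwdg$db),
                            bwd = list(W = bwdg$dW, b = bwdg$db)),
                att = att$grads,
                dense = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
  preds <- max.col(fwd$probs) - 1L
  list(loss = loss, grads = grads, moving = fwd$moving, preds = preds,
       probs = fwd$probs)
}
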