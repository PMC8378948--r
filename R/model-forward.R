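# Forward pass of the CRNN. Batches of B samples are processed as
# B*T stacked frames through the time-distributed conv stack (frame index
# n = (t-1)*B + b, b fastest), then reshaped to [B, T, features] for the
# recurrent stage.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

bn_eps <- 1e-3

#' One time-distributed convolution block (conv -> batch norm -> ReLU)
#'
#' The identical 3D kernel set is applied independently at every frame
#' (valid padding); batch normalization is computed per channel jointly
#' over batch, time and space, then ReLU.
#'
#' @param x Rank-5 array `[N, X, Y, Z, C_in]` (N = batch x time frames).
#' @param params Block parameter list (`w`, `b`, `gamma`, `beta`,
#'   `mov_mean`, `mov_var`).
#' @param config A [conv_block_config()].
#' @param training If `TRUE` use batch statistics (and report updated
#'   moving statistics); otherwise use the stored moving statistics.
#' @param keep_cache Keep intermediates needed for backpropagation.
#' @param bn_momentum Exponential-decay rate of the moving batch-norm
#'   statistics.
#' @return List with `out` (rank-5 array), `cache` and `moving` (updated
#'   moving statistics when training).
#' @export
conv_block_forward <- function(x, params, config, training = FALSE,
                               keep_cache = FALSE, bn_momentum = 0.99) {
  d <- dim(x)
  if (any(d[2:4] < config$kernel)) stop("kernel larger than input feature map")
  z <- conv3d_fwd_cpp(x, params$w, params$b, config$stride)
  dz <- dim(z)
  co <- dz[5]
  M <- matrix(z, ncol = co)
  if (training) {
    mu <- colMeans(M)
    vr <- colMeans(M * M) - mu * mu
    m <- bn_momentum
    moving <- list(mov_mean = m * params$mov_mean + (1 - m) * mu,
                   mov_var = m * params$mov_var + (1 - m) * vr)
  } else {
    mu <- params$mov_mean
    vr <- params$mov_var
    moving <- NULL
  }
  invstd <- 1 / sqrt(vr + bn_eps)
  nrw <- nrow(M)
  xhat <- (M - matrix(mu, nrw, co, byrow = TRUE)) *
    matrix(invstd, nrw, co, byrow = TRUE)
  y <- xhat * matrix(params$gamma, nrw, co, byrow = TRUE) +
    matrix(params$beta, nrw, co, byrow = TRUE)
  y <- relu(y)
  out <- array(y, dim = dz)
  cache <- if (keep_cache) {
    list(x = x, xhat = xhat, invstd = invstd, mu = mu,
         mask = y > 0, dims = dz)
  }
  list(out = out, cache = cache, moving = moving)
}

#' CNN stage: conv stack then squeeze to a per-frame feature sequence
#'
#' @param sample Rank-5 array `[T, X, Y, Z, C]` (a single sample, or a
#'   stacked batch of `B*T` frames).
#' @param params A `crnn_params` object (see [init_crnn_params()]).
#' @param config A [crnn_config()].
#' @param training Use batch statistics in batch norm.
#' @param keep_cache Keep intermediates for backpropagation.
#' @return List with `features` (matrix `[T, channels]` — per-frame feature
#'   vectors), `caches`, and `moving` (per-block updated moving stats when
#'   training). The pre-squeeze shape is `[T, 1, 1, 1, channels]`.
#' @export
cnn_forward <- function(sample, params, config, training = FALSE,
                        keep_cache = FALSE) {
  d <- dim(sample)
  if (is.null(d) || length(d) != 5L || !all(d[2:5] == config$input_shape[2:5])) {
    stop(sprintf("input shape [%s] does not match config [%s] on non-time axes",
                 paste(d, collapse = ","),
                 paste(config$input_shape, collapse = ",")))
  }
  x <- sample
  caches <- vector("list", length(config$conv_blocks))
  moving <- vector("list", length(config$conv_blocks))
  for (i in seq_along(config$conv_blocks)) {
    r <- conv_block_forward(x, params$conv[[i]], config$conv_blocks[[i]],
                            training = training, keep_cache = keep_cache,
                            bn_momentum = config$bn_momentum %||% 0.99)
    x <- r$out
    caches[[i]] <- r$cache
    moving[[i]] <- r$moving
  }
  dz <- dim(x)
  if (!all(dz[2:4] == 1L)) {
    stop(sprintf("conv stack did not collapse spatial dims: [%s]",
                 paste(dz, collapse = ",")))
  }
  list(features = matrix(x, nrow = dz[1], ncol = dz[5]),
       caches = caches, moving = moving)
}

#' One LSTM cell step
#'
#' Gate equations: `f, i, o = sigmoid(W . [x_t, h_prev] + b)` per gate,
#' candidate `ctilde = tanh(...)`, `c_t = f*c_prev + i*ctilde`,
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t Input at time t: vector `[in]` or matrix `[B, in]`.
#' @param h_prev,c_prev Previous hidden / cell state, same leading shape.
#' @param params List with `W` (`[in + H, 4H]`, gate column order f, i, c,
#'   o) and `b` (`[4H]`).
#' @return List with `h`, `c` (and gate intermediates `f`, `i`, `g`, `o`,
#'   `tanh_c` used by backpropagation).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, nrow = 1)
    h_prev <- matrix(h_prev, nrow = 1)
    c_prev <- matrix(c_prev, nrow = 1)
  }
  H <- ncol(h_prev)
  B <- nrow(x_t)
  Z <- cbind(x_t, h_prev) %*% params$W +
    matrix(params$b, B, 4 * H, byrow = TRUE)
  f <- sigmoid(Z[, 1:H, drop = FALSE])
  i <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
  cc <- f * c_prev + i * g
  tc <- tanh(cc)
  h <- o * tc
  if (vec_in) {
    list(h = drop(h), c = drop(cc), f = drop(f), i = drop(i), g = drop(g),
         o = drop(o), tanh_c = drop(tc))
  } else {
    list(h = h, c = cc, f = f, i = i, g = g, o = o, tanh_c = tc)
  }
}

# One direction over [B, T, IN]; returns H [B, T, Hd] and per-step caches.
lstm_dir_forward <- function(X3, params, keep_cache = FALSE) {
  B <- dim(X3)[1]
  T_len <- dim(X3)[2]
  Hd <- length(params$b) / 4L
  h <- matrix(0, B, Hd)
  cc <- matrix(0, B, Hd)
  Hout <- array(0, c(B, T_len, Hd))
  caches <- if (keep_cache) vector("list", T_len)
  for (t in seq_len(T_len)) {
    x_t <- matrix(X3[, t, ], nrow = B)
    st <- lstm_step(x_t, h, cc, params)
    if (keep_cache) {
      caches[[t]] <- list(x = x_t, h_prev = h, c_prev = cc, f = st$f,
                          i = st$i, g = st$g, o = st$o, tanh_c = st$tanh_c)
    }
    h <- st$h
    cc <- st$c
    Hout[, t, ] <- h
  }
  list(H = Hout, caches = caches)
}

#' Bidirectional LSTM over a feature sequence
#'
#' Runs one LSTM forward over t = 1..T and a second over the reversed
#' sequence, both from zero initial states, and concatenates their per-step
#' hidden states. Dropout (inverted scaling) is applied to the concatenated
#' outputs only when `dropout_active`.
#'
#' @param seq Matrix `[T, in]` (one sequence) or array `[B, T, in]`.
#' @param params List with `fwd` and `bwd` direction parameters (see
#'   [lstm_step()]).
#' @param dropout_active Apply dropout (training mode).
#' @param dropout_rate Dropout probability (default 0.2).
#' @param keep_cache Keep intermediates for backpropagation.
#' @return For matrix input, a matrix `[T, 2H]`; for array input a list
#'   with `H` (`[B, T, 2H]`), `cache` and the dropout `mask`.
#' @export
bilstm_forward <- function(seq, params, dropout_active = FALSE,
                           dropout_rate = 0.2, keep_cache = FALSE) {
  # single-sequence input arrives as [T, in]; batch input as [B, T, in]
  mat_in <- length(dim(seq)) == 2L
  X3 <- if (mat_in) aperm(array(seq, c(dim(seq), 1L)), c(3L, 1L, 2L)) else seq
  T_len <- dim(X3)[2]
  fw <- lstm_dir_forward(X3, params$fwd, keep_cache)
  Xr <- X3[, rev(seq_len(T_len)), , drop = FALSE]
  bwr <- lstm_dir_forward(Xr, params$bwd, keep_cache)
  Hb <- bwr$H[, rev(seq_len(T_len)), , drop = FALSE]
  Hd <- dim(fw$H)[3]
  B <- dim(X3)[1]
  H <- array(0, c(B, T_len, 2L * Hd))
  H[, , seq_len(Hd)] <- fw$H
  H[, , Hd + seq_len(Hd)] <- Hb
  mask <- NULL
  if (dropout_active && dropout_rate > 0) {
    keep <- 1 - dropout_rate
    mask <- array(rbinom(length(H), 1L, keep) / keep, dim(H))
    H <- H * mask
  }
  if (mat_in) return(matrix(H[1, , ], nrow = T_len))
  list(H = H, cache = list(fw = fw$caches, bw = bwr$caches, T_len = T_len),
       mask = mask)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Attention pooling of a hidden-state sequence
#'
#' Additive scoring (default): `s_j = ua' tanh(Wa h_j + ba)`, weights
#' `w = softmax(s)` over time, context `c = sum_j w_j h_j`. The literal
#' variant is parameter-free: weights are an elementwise softmax of the
#' hidden values themselves along time.
#'
#' @param H Matrix `[T, F]` (one sequence) or array `[B, T, F]`.
#' @param params Attention parameters (`Wa`, `ba`, `ua`); ignored for the
#'   literal variant.
#' @param type `"additive"` or `"literal"`.
#' @param keep_cache Keep intermediates for backpropagation.
#' @return For matrix input, list with `context` (`[F]`) and `weights`
#'   (`[T]`, non-negative, summing to 1; `[T, F]` for the literal variant).
#'   For array input the batched analogue plus `cache`.
#' @export
attention_pool <- function(H, params = NULL, type = c("additive", "literal"),
                           keep_cache = FALSE) {
  type <- match.arg(type)
  mat_in <- length(dim(H)) == 2L
  H3 <- if (mat_in) aperm(array(H, c(dim(H), 1L)), c(3L, 1L, 2L)) else H
  B <- dim(H3)[1]
  T_len <- dim(H3)[2]
  Fd <- dim(H3)[3]
  Hflat <- matrix(H3, B * T_len, Fd)  # row (t-1)*B + b
  if (type == "additive") {
    pre <- Hflat %*% params$Wa +
      matrix(params$ba, B * T_len, length(params$ba), byrow = TRUE)
    U <- tanh(pre)
    s <- matrix(as.vector(U %*% params$ua), B, T_len)
    W <- softmax_rows(s)
  } else {
    # elementwise softmax along time, per feature
    W3 <- array(0, dim(H3))
    for (f in seq_len(Fd)) W3[, , f] <- softmax_rows(matrix(H3[, , f], B, T_len))
    U <- NULL
  }
  ctx <- matrix(0, B, Fd)
  if (type == "additive") {
    for (t in seq_len(T_len)) ctx <- ctx + W[, t] * matrix(H3[, t, ], B, Fd)
  } else {
    for (t in seq_len(T_len)) ctx <- ctx + matrix(W3[, t, ] * H3[, t, ], B, Fd)
  }
  if (mat_in) {
    return(list(context = drop(ctx),
                weights = if (type == "additive") drop(W) else
                  matrix(W3[1, , ], T_len, Fd)))
  }
  cache <- if (keep_cache) {
    if (type == "additive") list(H3 = H3, Hflat = Hflat, U = U, W = W)
    else list(H3 = H3, W3 = W3)
  }
  list(context = ctx, weights = if (type == "additive") W else W3,
       cache = cache)
}

#' Classifier head: dense-ReLU-dense-softmax
#'
#' @param context Feature vector `[F]` or matrix `[B, F]`.
#' @param params Dense parameters (`W1`, `b1`, `W2`, `b2`).
#' @param keep_cache Keep intermediates for backpropagation.
#' @return List with `probs` (summing to 1 per row), `logits` and `hidden`.
#' @export
classify <- function(context, params, keep_cache = FALSE) {
  vec_in <- is.null(dim(context))
  Cm <- if (vec_in) matrix(context, nrow = 1) else context
  B <- nrow(Cm)
  h <- relu(Cm %*% params$W1 + matrix(params$b1, B, length(params$b1), byrow = TRUE))
  logits <- h %*% params$W2 + matrix(params$b2, B, length(params$b2), byrow = TRUE)
  probs <- softmax_rows(logits)
  if (vec_in) {
    list(probs = drop(probs), logits = drop(logits), hidden = drop(h))
  } else {
    list(probs = probs, logits = logits, hidden = h,
         cache = if (keep_cache) list(context = Cm, hidden = h))
  }
}

#' Cross-entropy loss from logits
#'
#' Numerically stable `-log softmax(logits)[true class]`.
#'
#' @param logits Vector `[K]` or matrix `[B, K]` of unnormalized scores.
#' @param one_hot One-hot label vector/matrix of the same shape.
#' @return Mean loss (scalar, >= 0).
#' @export
cross_entropy <- function(logits, one_hot) {
  L <- if (is.null(dim(logits))) matrix(logits, nrow = 1) else logits
  Y <- if (is.null(dim(one_hot))) matrix(one_hot, nrow = 1) else one_hot
  stopifnot(all(dim(L) == dim(Y)))
  m <- apply(L, 1, max)
  lse <- m + log(rowSums(exp(L - m)))
  mean(lse - rowSums(Y * L))
}

# Stack B samples (each [T, X, Y, Z, C]) into a [B*T, X, Y, Z, C] frame
# array with frame index n = (t-1)*B + b.
stack_samples <- function(xs) {
  B <- length(xs)
  d <- dim(xs[[1]])
  T_len <- d[1]
  out <- array(0, c(B * T_len, d[2], d[3], d[4], d[5]))
  for (b in seq_len(B)) {
    out[b + B * (seq_len(T_len) - 1L), , , , ] <- xs[[b]]
  }
  out
}

#' Full CRNN forward pass
#'
#' @param xs List of rank-5 sample arrays `[T, X, Y, Z, 1]` (a batch), or a
#'   single such array.
#' @param params A `crnn_params`.
#' @param config A [crnn_config()].
#' @param training Training mode: batch-norm batch statistics and dropout.
#' @param keep_cache Keep every intermediate for backpropagation.
#' @return List with `probs` (`[B, K]`), `logits`, `attention_weights`, and
#'   (when requested) `cache` / `moving`.
#' @export
crnn_forward <- function(xs, params, config, training = FALSE,
                         keep_cache = FALSE) {
  if (!is.list(xs)) xs <- list(xs)
  B <- length(xs)
  T_len <- dim(xs[[1]])[1]
  xb <- stack_samples(xs)
  cnn <- cnn_forward(xb, params, config, training = training,
                     keep_cache = keep_cache)
  X3 <- array(cnn$features, c(B, T_len, ncol(cnn$features)))
  bl <- bilstm_forward(X3, params$lstm,
                       dropout_active = training && config$lstm_dropout > 0,
                       dropout_rate = config$lstm_dropout,
                       keep_cache = keep_cache)
  att <- attention_pool(bl$H, params$att, type = config$attention_type,
                        keep_cache = keep_cache)
  cls <- classify(att$context, params$dense, keep_cache = keep_cache)
  list(probs = cls$probs, logits = cls$logits,
       attention_weights = att$weights,
       cache = if (keep_cache) list(B = B, T_len = T_len, cnn = cnn,
                                    bilstm = bl, att = att, cls = cls),
       moving = cnn$moving)
}
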