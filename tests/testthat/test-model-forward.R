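# Forward-pass semantics: each stage checked against an independent
# brute-force oracle or an analytic limit.

test_that("a time-distributed conv block equals per-frame naive 3D convolution", {
  set.seed(21)
  cfgb <- conv_block_config(c(3, 3, 3), 2, 2)
  params <- list(w = array(rnorm(3 * 3 * 3 * 1 * 2), c(3, 3, 3, 1, 2)),
                 b = rnorm(2), gamma = c(1, 1), beta = c(0, 0),
                 mov_mean = c(0, 0), mov_var = c(1, 1))
  x <- array(rnorm(4 * 7 * 8 * 7), c(4, 7, 8, 7, 1))
  # identity BN (moving mean 0, var 1, eps absorbed below), inference mode
  out <- conv_block_forward(x, params, cfgb, training = FALSE)$out
  scale <- 1 / sqrt(1 + 1e-3)  # BN with identity stats still divides by sqrt(var+eps)
  for (t in 1:4) {
    frame <- array(x[t, , , , ], c(7, 8, 7, 1))
    ref <- naive_conv3d_frame(frame, params$w, params$b, 2) * scale
    ref[ref < 0] <- 0
    expect_equal(array(out[t, , , , ], dim(ref)), ref, tolerance = 1e-5)
  }
})

test_that("a 1x1x1 identity block with identity batch norm passes input through", {
  cfgb <- conv_block_config(c(1, 1, 1), 1, 1)
  params <- list(w = array(1, c(1, 1, 1, 1, 1)), b = 0, gamma = sqrt(1 + 1e-3),
                 beta = 0, mov_mean = 0, mov_var = 1)
  x <- array(runif(3 * 4 * 4 * 4), c(3, 4, 4, 4, 1))
  out <- conv_block_forward(x, params, cfgb, training = FALSE)$out
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("permuting input frames permutes CNN feature rows identically", {
  cfg <- tiny_config()
  p <- init_crnn_params(cfg, seed = 3)
  x <- tiny_samples(1, cfg, seed = 5)[[1]]
  perm <- c(3L, 1L, 4L, 2L)
  xp <- x[perm, , , , , drop = FALSE]
  f1 <- cnn_forward(x, p, cfg)$features
  f2 <- cnn_forward(xp, p, cfg)$features
  expect_equal(f2, f1[perm, ], tolerance = 1e-12)
})

test_that("an all-zero input with zero biases yields all-zero CNN features", {
  cfg <- tiny_config()
  p <- init_crnn_params(cfg, seed = 3)
  for (i in seq_along(p$conv)) p$conv[[i]]$b[] <- 0
  x <- array(0, cfg$input_shape)
  expect_true(all(cnn_forward(x, p, cfg)$features == 0))
})

test_that("the LSTM step follows the gate equations", {
  # all-zero parameters: every gate sigmoid(0) = 0.5, tanh(0) = 0
  H <- 3
  p0 <- list(W = array(0, c(2 + H, 4 * H)), b = numeric(4 * H))
  st <- lstm_step(c(1, -1), numeric(H), numeric(H), p0)
  expect_equal(st$f, rep(0.5, H))
  expect_equal(st$i, rep(0.5, H))
  expect_equal(st$o, rep(0.5, H))
  expect_equal(st$c, numeric(H))
  expect_equal(st$h, numeric(H))
  # saturated forget gate with zero input weights: perfect memory
  psat <- list(W = array(0, c(2 + H, 4 * H)), b = c(rep(50, H), rep(-50, 3 * H)))
  c_prev <- c(0.3, -0.8, 1.2)
  expect_equal(lstm_step(c(1, 1), numeric(H), c_prev, psat)$c, c_prev,
               tolerance = 1e-9)
  # random instance vs scalar oracle
  set.seed(31)
  p <- list(W = array(rnorm(5 * 12, sd = 0.5), c(5, 12)), b = rnorm(12))
  x <- rnorm(2); h <- rnorm(3); cc <- rnorm(3)
  got <- lstm_step(x, h, cc, p)
  ref <- scalar_lstm_step(x, h, cc, p$W, p$b)
  expect_equal(got$h, ref$h, tolerance = 1e-6)
  expect_equal(got$c, ref$c, tolerance = 1e-6)
})

test_that("the bidirectional LSTM unrolls both directions against the step oracle", {
  set.seed(32)
  IN <- 2; H <- 3; T_len <- 5
  params <- list(
    fwd = list(W = array(rnorm((IN + H) * 4 * H, sd = 0.4), c(IN + H, 4 * H)),
               b = rnorm(4 * H)),
    bwd = list(W = array(rnorm((IN + H) * 4 * H, sd = 0.4), c(IN + H, 4 * H)),
               b = rnorm(4 * H)))
  X <- matrix(rnorm(T_len * IN), T_len, IN)
  out <- bilstm_forward(X, params)
  expect_identical(dim(out), c(5L, 6L))
  # forward half by scalar recursion
  h <- numeric(H); cc <- numeric(H)
  for (t in 1:T_len) {
    st <- scalar_lstm_step(X[t, ], h, cc, params$fwd$W, params$fwd$b)
    h <- st$h; cc <- st$c
    expect_equal(out[t, 1:H], h, tolerance = 1e-8)
  }
  # backward half by scalar recursion over the reversed sequence
  h <- numeric(H); cc <- numeric(H)
  for (t in T_len:1) {
    st <- scalar_lstm_step(X[t, ], h, cc, params$bwd$W, params$bwd$b)
    h <- st$h; cc <- st$c
    expect_equal(out[t, H + 1:H], h, tolerance = 1e-8)
  }
})

test_that("reversing the sequence with swapped directions mirrors the BiLSTM output", {
  set.seed(33)
  IN <- 2; H <- 3; T_len <- 6
  mk <- function() list(W = array(rnorm((IN + H) * 4 * H, sd = 0.4), c(IN + H, 4 * H)),
                        b = rnorm(4 * H))
  params <- list(fwd = mk(), bwd = mk())
  swapped <- list(fwd = params$bwd, bwd = params$fwd)
  X <- matrix(rnorm(T_len * IN), T_len, IN)
  a <- bilstm_forward(X, params)
  b <- bilstm_forward(X[T_len:1, ], swapped)
  expect_equal(b[, c(H + 1:H, 1:H)], a[T_len:1, ], tolerance = 1e-10)
})

test_that("BiLSTM evaluation without dropout is deterministic", {
  cfg <- tiny_config()
  p <- init_crnn_params(cfg, seed = 4)
  X <- matrix(rnorm(4 * 3), 4, 3)
  expect_identical(bilstm_forward(X, p$lstm, dropout_active = FALSE),
                   bilstm_forward(X, p$lstm, dropout_active = FALSE))
})

test_that("attention weights form a simplex and reduce to known limits", {
  set.seed(34)
  Fd <- 6; A <- 3; T_len <- 20
  params <- list(Wa = array(rnorm(Fd * A, sd = 0.3), c(Fd, A)),
                 ba = rnorm(A), ua = rnorm(A))
  # identical rows: uniform weights and context equal to the common vector
  h <- rnorm(Fd)
  H <- matrix(h, T_len, Fd, byrow = TRUE)
  ap <- attention_pool(H, params)
  expect_equal(ap$weights, rep(1 / T_len, T_len), tolerance = 1e-12)
  expect_equal(ap$context, h, tolerance = 1e-12)
  # random input: non-negative weights summing to 1
  for (r in 1:5) {
    ap <- attention_pool(matrix(rnorm(T_len * Fd), T_len, Fd), params)
    expect_true(all(ap$weights >= 0))
    expect_lt(abs(sum(ap$weights) - 1), 1e-6)
  }
})

test_that("a 2-step additive attention toy matches hand-computed scores", {
  Wa <- matrix(c(1, 0, 0, 1), 2, 2)  # identity projection
  params <- list(Wa = Wa, ba = c(0, 0), ua = c(1, -1))
  H <- rbind(c(0.5, -0.2), c(-0.3, 0.4))
  s <- c(tanh(0.5) - tanh(-0.2), tanh(-0.3) - tanh(0.4))
  w <- exp(s) / sum(exp(s))
  ref <- w[1] * H[1, ] + w[2] * H[2, ]
  ap <- attention_pool(H, params)
  expect_equal(ap$weights, w, tolerance = 1e-8)
  expect_equal(ap$context, ref, tolerance = 1e-8)
})

test_that("literal attention is an elementwise softmax over time", {
  H <- rbind(c(1, -1), c(2, 0), c(0, 1))
  ap <- attention_pool(H, type = "literal")
  for (f in 1:2) {
    w <- exp(H[, f]) / sum(exp(H[, f]))
    expect_equal(ap$weights[, f], w, tolerance = 1e-10)
    expect_equal(ap$context[f], sum(w * H[, f]), tolerance = 1e-10)
  }
})

test_that("the classifier softmax is a proper distribution with known limits", {
  D <- 4; K <- 7; Fd <- 6
  zero <- list(W1 = array(0, c(Fd, D)), b1 = numeric(D),
               W2 = array(0, c(D, K)), b2 = numeric(K))
  out <- classify(rnorm(Fd), zero)
  expect_equal(out$probs, rep(1 / 7, 7), tolerance = 1e-12)
  set.seed(35)
  p <- list(W1 = array(rnorm(Fd * D), c(Fd, D)), b1 = rnorm(D),
            W2 = array(rnorm(D * K), c(D, K)), b2 = rnorm(K))
  for (r in 1:5) {
    pr <- classify(rnorm(Fd), p)$probs
    expect_true(all(pr > 0 & pr < 1))
    expect_lt(abs(sum(pr) - 1), 1e-6)
  }
})

test_that("cross-entropy matches its defining formula and shift invariance", {
  one_hot <- c(0, 0, 1, 0, 0, 0, 0)
  expect_equal(cross_entropy(numeric(7), one_hot), log(7), tolerance = 1e-12)
  strong <- c(rep(-50, 2), 50, rep(-50, 4))
  expect_lt(cross_entropy(strong, one_hot), 1e-8)
  set.seed(36)
  for (r in 1:5) {
    logits <- rnorm(7, sd = 3)
    p <- exp(logits) / sum(exp(logits))
    expect_equal(cross_entropy(logits, one_hot), -log(p[3]), tolerance = 1e-8)
    expect_equal(cross_entropy(logits + 11.3, one_hot),
                 cross_entropy(logits, one_hot), tolerance = 1e-8)
  }
})

test_that("the full forward pass is deterministic with dropout disabled", {
  cfg <- tiny_config()
  p <- init_crnn_params(cfg, seed = 8)
  xs <- tiny_samples(3, cfg, seed = 9)
  a <- crnn_forward(xs, p, cfg, training = FALSE)
  b <- crnn_forward(xs, p, cfg, training = FALSE)
  expect_identical(a$probs, b$probs)
  expect_identical(dim(a$probs), c(3L, 3L))
  expect_equal(rowSums(a$probs), rep(1, 3), tolerance = 1e-9)
})
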