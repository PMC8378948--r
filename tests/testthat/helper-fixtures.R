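# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no binary fixtures.

# A tiny CRNN whose conv stack collapses 7x8x7 -> 3x3x3 -> 1x1x1.
tiny_config <- function(n_classes = 3L, lstm_dropout = 0) {
  crnn_config(
    conv_blocks = list(conv_block_config(c(3, 3, 3), 2, 2),
                       conv_block_config(c(3, 3, 3), 3, 1)),
    lstm_units = 3L, attention_dim = 2L, dense_units = 4L,
    n_classes = n_classes, input_shape = c(4L, 7L, 8L, 7L, 1L),
    lstm_dropout = lstm_dropout)
}

tiny_samples <- function(n, config = tiny_config(), seed = 1) {
  withr::with_seed(seed, {
    d <- config$input_shape
    lapply(seq_len(n), function(i) array(runif(prod(d)), d))
  })
}

# A synthetic block clip with known content: voxel value = frame index.
ramp_clip <- function(n_frames = 36L, sp = c(4L, 5L, 4L),
                      subject = "sub-01", label = 0L) {
  data <- array(rep(seq_len(n_frames) - 1, each = prod(sp)), c(sp, n_frames))
  structure(list(data = data, subject_id = subject, task_name = "Emotion",
                 label = label, onset_frame = 0L),
            class = "block_clip")
}

# Independent oracle: naive 3D valid convolution of a single frame, plain
# R loops, no shared code with the package kernels.
naive_conv3d_frame <- function(vol, w, b, stride) {
  k <- dim(w)[1:3]
  ci <- dim(w)[4]
  co <- dim(w)[5]
  sp <- dim(vol)[1:3]
  od <- (sp - k) %/% stride + 1L
  out <- array(0, c(od, co))
  for (c_out in seq_len(co)) {
    for (zo in seq_len(od[3])) for (yo in seq_len(od[2])) for (xo in seq_len(od[1])) {
      acc <- b[c_out]
      for (c_in in seq_len(ci)) {
        patch <- vol[(xo - 1) * stride + seq_len(k[1]),
                     (yo - 1) * stride + seq_len(k[2]),
                     (zo - 1) * stride + seq_len(k[3]), c_in]
        acc <- acc + sum(patch * w[, , , c_in, c_out])
      }
      out[xo, yo, zo, c_out] <- acc
    }
  }
  out
}

# Independent oracle: scalar evaluation of the LSTM gate equations.
scalar_lstm_step <- function(x, h_prev, c_prev, W, b) {
  H <- length(h_prev)
  z <- as.numeric(c(x, h_prev) %*% W) + b
  sig <- function(u) 1 / (1 + exp(-u))
  f <- sig(z[1:H])
  i <- sig(z[(H + 1):(2 * H)])
  g <- tanh(z[(2 * H + 1):(3 * H)])
  o <- sig(z[(3 * H + 1):(4 * H)])
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

# Small separable synthetic dataset shared by the training tests.
easy_sim_config <- function(n_subjects, seed = 11) {
  sim_config(spatial_shape = c(24L, 28L, 24L), n_subjects = n_subjects,
             effect_amplitude = 0.5, noise_sd = 0.2, drift_amplitude = 0,
             seed = seed)
}
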