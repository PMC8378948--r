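# CRNN architecture configuration and the analytic inspectors (shape chain
# and parameter tallies). The inspectors never allocate tensors.

#' Configuration of one 3D convolution block
#'
#' Each block is a valid-padding (no padding) 3D convolution applied
#' time-distributed, followed by batch normalization and ReLU.
#'
#' @param kernel Integer length-3 kernel size `(kx, ky, kz)`.
#' @param channels Output channel count.
#' @param stride Isotropic stride (>= 1).
#' @return Object of class `conv_block_config`.
#' @export
conv_block_config <- function(kernel, channels, stride = 1L) {
  kernel <- as.integer(kernel)
  stopifnot(length(kernel) == 3, all(kernel >= 1), channels >= 1, stride >= 1)
  structure(list(kernel = kernel, channels = as.integer(channels),
                 stride = as.integer(stride), padding = "valid"),
            class = "conv_block_config")
}

#' Full CRNN hyperparameter configuration
#'
#' Defaults reproduce the published architecture: four conv blocks
#' (7x7x7/32/stride 2, 3x3x3/64/stride 2, 3x3x3/64/stride 2, and a final
#' "full convolution" 8x10x8/64/stride 1 whose kernel equals the incoming
#' feature-map size), a single bidirectional LSTM layer with 64 units per
#' direction and dropout 0.2 on its outputs, additive attention with a
#' 64-dimensional tanh projection, a 64-unit dense layer, and a 7-way
#' softmax. Strides of 2 replace pooling; there are no pooling layers.
#'
#' @param conv_blocks List of [conv_block_config()]s.
#' @param lstm_units LSTM units per direction.
#' @param lstm_dropout Dropout rate applied to BiLSTM outputs in training.
#' @param attention_dim Width of the attention tanh projection.
#' @param attention_type `"additive"` (default; learned projection + context
#'   vector) or `"literal"` (parameter-free elementwise softmax over the
#'   hidden vectors themselves).
#' @param dense_units Hidden units of the first classifier layer.
#' @param n_classes Number of task states (7).
#' @param input_shape Length-5 integer `(T, X, Y, Z, C)`.
#' @param bn_momentum Exponential-decay rate of the batch-norm moving
#'   statistics (default 0.99; reduced desk-scale models, which take far
#'   fewer optimizer steps per epoch, use 0.9 so the inference statistics
#'   track the batch statistics within a few epochs).
#' @return Object of class `crnn_config`.
#' @export
#' @examples
#' cfg <- crnn_config()
#' shape_chain(cfg)
#' count_parameters(cfg)
crnn_config <- function(conv_blocks = list(
                          conv_block_config(c(7, 7, 7), 32, 2),
                          conv_block_config(c(3, 3, 3), 64, 2),
                          conv_block_config(c(3, 3, 3), 64, 2),
                          conv_block_config(c(8, 10, 8), 64, 1)),
                        lstm_units = 64L, lstm_dropout = 0.2,
                        attention_dim = 64L,
                        attention_type = c("additive", "literal"),
                        dense_units = 64L, n_classes = 7L,
                        input_shape = c(20L, 78L, 93L, 76L, 1L),
                        bn_momentum = 0.99) {
  attention_type <- match.arg(attention_type)
  stopifnot(length(input_shape) == 5, n_classes >= 2, lstm_units >= 1,
            attention_dim >= 1, dense_units >= 1,
            lstm_dropout >= 0, lstm_dropout < 1)
  for (b in conv_blocks) stopifnot(inherits(b, "conv_block_config"))
  cfg <- structure(list(conv_blocks = conv_blocks,
                        lstm_units = as.integer(lstm_units),
                        lstm_dropout = lstm_dropout,
                        attention_dim = as.integer(attention_dim),
                        attention_type = attention_type,
                        dense_units = as.integer(dense_units),
                        n_classes = as.integer(n_classes),
                        input_shape = as.integer(input_shape),
                        bn_momentum = bn_momentum),
                   class = "crnn_config")
  sc <- shape_chain(cfg)  # validates the conv arithmetic
  last <- cfg$conv_blocks[[length(cfg$conv_blocks)]]
  entering <- sc$shapes[[length(cfg$conv_blocks)]][2:4]
  if (!all(last$kernel == entering)) {
    stop(sprintf(
      "last conv block must be a full convolution: kernel %s != entering feature map %s",
      paste(last$kernel, collapse = "x"), paste(entering, collapse = "x")))
  }
  cfg
}

#' Reduced-scale CRNN configuration for desk-size experiments
#'
#' Same topology as [crnn_config()] but sized for simulated 24 x 28 x 24
#' volumes (cropped to 20 x 24 x 20): conv stack 5x5x5/8/s2 ->
#' 3x3x3/16/s2 -> full 3x4x3/16, 16 LSTM units per direction, 16-dim
#' attention, 16 dense units.
#'
#' @param input_shape Length-5 integer shape (default `c(20, 20, 24, 20, 1)`).
#' @return A `crnn_config`.
#' @export
reduced_crnn_config <- function(input_shape = c(20L, 20L, 24L, 20L, 1L)) {
  sp <- input_shape[2:4]
  o1 <- (sp - 5L) %/% 2L + 1L
  o2 <- (o1 - 3L) %/% 2L + 1L
  crnn_config(
    conv_blocks = list(
      conv_block_config(c(5, 5, 5), 8, 2),
      conv_block_config(c(3, 3, 3), 16, 2),
      conv_block_config(o2, 16, 1)),
    lstm_units = 16L, attention_dim = 16L, dense_units = 16L,
    input_shape = as.integer(input_shape), bn_momentum = 0.9)
}

conv_out_dim <- function(n, k, s) (n - k) %/% s + 1L

#' Per-stage output shapes of the CRNN
#'
#' Valid-padding arithmetic `floor((n - k)/s) + 1` per spatial axis and
#' stage, from the rank-5 input down to the class logits. For the default
#' configuration the CNN terminates at `[20, 1, 1, 1, 64]`.
#'
#' @param config A [crnn_config()].
#' @return Object of class `shape_chain_report`: named list of shapes.
#' @export
shape_chain <- function(config) {
  stopifnot(length(config$input_shape) == 5)
  T_len <- config$input_shape[1]
  sp <- config$input_shape[2:4]
  ch <- config$input_shape[5]
  shapes <- list(input = config$input_shape)
  for (i in seq_along(config$conv_blocks)) {
    b <- config$conv_blocks[[i]]
    if (any(sp < b$kernel)) {
      stop(sprintf("conv%d kernel %s exceeds its %s input feature map",
                   i, paste(b$kernel, collapse = "x"),
                   paste(sp, collapse = "x")))
    }
    sp <- conv_out_dim(sp, b$kernel, b$stride)
    ch <- b$channels
    shapes[[paste0("conv", i)]] <- c(T_len, sp, ch)
  }
  shapes[["squeeze"]] <- c(T_len, ch)
  shapes[["bilstm"]] <- c(T_len, 2L * config$lstm_units)
  shapes[["attention"]] <- 2L * config$lstm_units
  shapes[["dense"]] <- config$dense_units
  shapes[["logits"]] <- config$n_classes
  structure(list(shapes = shapes), class = "shape_chain_report")
}

#' @export
print.shape_chain_report <- function(x, ...) {
  cat("Stage      Output shape\n")
  for (nm in names(x$shapes)) {
    cat(sprintf("%-10s [%s]\n", nm, paste(x$shapes[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Analytic parameter tally of the CRNN
#'
#' Counts every learned entry without allocating tensors: each conv block
#' contributes `kx*ky*kz*C_in*C_out + C_out` kernel and bias entries plus
#' batch-norm scale/shift (trainable) and moving mean/variance
#' (non-trainable), 2 per channel each; each LSTM direction contributes
#' `4*((in + H)*H + H)` (one bias vector per gate); additive attention
#' contributes `2H*A + A + A`; the classifier `2H*D + D + D*K + K`. The
#' default configuration totals 2,882,503 parameters of which 2,882,055
#' are trainable.
#'
#' @param config A [crnn_config()].
#' @return Object of class `param_count_report` with a per-layer data frame
#'   and `total`, `trainable`, `non_trainable` fields.
#' @export
count_parameters <- function(config) {
  sc <- shape_chain(config)
  rows <- list()
  add <- function(name, trainable, non_trainable = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = name, trainable = trainable, non_trainable = non_trainable)
  }
  c_in <- config$input_shape[5]
  for (i in seq_along(config$conv_blocks)) {
    b <- config$conv_blocks[[i]]
    add(sprintf("conv%d (%s, %d ch, stride %d)", i,
                paste(b$kernel, collapse = "x"), b$channels, b$stride),
        prod(b$kernel) * c_in * b$channels + b$channels)
    add(sprintf("batchnorm%d", i), 2 * b$channels, 2 * b$channels)
    c_in <- b$channels
  }
  H <- config$lstm_units
  per_dir <- 4 * ((c_in + H) * H + H)
  add("bilstm (forward)", per_dir)
  add("bilstm (backward)", per_dir)
  if (config$attention_type == "additive") {
    A <- config$attention_dim
    add("attention", 2 * H * A + A + A)
  } else {
    add("attention", 0)
  }
  D <- config$dense_units
  add("dense", 2 * H * D + D)
  add("classifier", D * config$n_classes + config$n_classes)
  tab <- do.call(rbind, rows)
  structure(list(layers = tab,
                 trainable = sum(tab$trainable),
                 non_trainable = sum(tab$non_trainable),
                 total = sum(tab$trainable) + sum(tab$non_trainable)),
            class = "param_count_report")
}

#' @export
print.param_count_report <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat(sprintf("Total: %s (trainable %s, non-trainable %s)\n",
              format(x$total, big.mark = ","),
              format(x$trainable, big.mark = ","),
              format(x$non_trainable, big.mark = ",")))
  invisible(x)
}
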