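# Parameter containers for the CRNN. Weights are Glorot-uniform; LSTM
# forget-gate biases start at 1 (standard recurrent initialization); batch
# norm starts at identity with zero moving mean and unit moving variance.

glorot <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

#' Initialize CRNN parameters
#'
#' @param config A [crnn_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return Nested parameter list (class `crnn_params`) with components
#'   `conv` (per block: `w`, `b`, `gamma`, `beta`, `mov_mean`, `mov_var`),
#'   `lstm` (`fwd`/`bwd`, each `W` `[in + H, 4H]` with gate order f, i, c, o
#'   and bias `b`), `att` (`Wa`, `ba`, `ua`; empty for literal attention)
#'   and `dense` (`W1`, `b1`, `W2`, `b2`).
#' @export
init_crnn_params <- function(config, seed = NULL) {
  with_seed(seed, {
    c_in <- config$input_shape[5]
    conv <- lapply(config$conv_blocks, function(b) {
      k <- b$kernel
      co <- b$channels
      p <- list(
        w = glorot(c(k, c_in, co), prod(k) * c_in, prod(k) * co),
        b = numeric(co),
        gamma = rep(1, co), beta = numeric(co),
        mov_mean = numeric(co), mov_var = rep(1, co))
      c_in <<- co
      p
    })
    H <- config$lstm_units
    lstm_dir <- function(input_dim) {
      b <- numeric(4 * H)
      b[1:H] <- 1  # forget gate bias
      list(W = glorot(c(input_dim + H, 4 * H), input_dim + H, 4 * H), b = b)
    }
    feat <- config$conv_blocks[[length(config$conv_blocks)]]$channels
    att <- if (config$attention_type == "additive") {
      A <- config$attention_dim
      list(Wa = glorot(c(2 * H, A), 2 * H, A), ba = numeric(A),
           ua = glorot(c(A), A, 1))
    } else {
      list()
    }
    D <- config$dense_units
    structure(list(
      conv = conv,
      lstm = list(fwd = lstm_dir(feat), bwd = lstm_dir(feat)),
      att = att,
      dense = list(W1 = glorot(c(2 * H, D), 2 * H, D), b1 = numeric(D),
                   W2 = glorot(c(D, config$n_classes), D, config$n_classes),
                   b2 = numeric(config$n_classes))
    ), class = "crnn_params")
  })
}

# Trainable leaves in a fixed traversal order, as list of index paths
# (kept as lists so integer indices are not coerced to names).
trainable_paths <- function(params) {
  paths <- list()
  for (i in seq_along(params$conv)) {
    for (nm in c("w", "b", "gamma", "beta")) {
      paths[[length(paths) + 1L]] <- list("conv", i, nm)
    }
  }
  for (dir in c("fwd", "bwd")) {
    for (nm in c("W", "b")) paths[[length(paths) + 1L]] <- list("lstm", dir, nm)
  }
  for (nm in names(params$att)) paths[[length(paths) + 1L]] <- list("att", nm)
  for (nm in c("W1", "b1", "W2", "b2")) {
    paths[[length(paths) + 1L]] <- list("dense", nm)
  }
  paths
}

get_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

set_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1]]]] <- value
  } else {
    x[[path[[1]]]] <- set_path(x[[path[[1]]]], path[-1], value)
  }
  x
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the parameters, the full configuration and the
#' initialization seed, so a run can be reproduced from the file alone.
#'
#' @param params A `crnn_params` object.
#' @param config The [crnn_config()] the parameters belong to.
#' @param path File path (`.rds`).
#' @param seed Seed recorded for provenance (may be `NULL`).
#' @param extra Optional list of extra metadata (e.g. training history).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `params`, `config`, `seed` and `extra`.
#' @export
save_checkpoint <- function(params, config, path, seed = NULL, extra = NULL) {
  saveRDS(list(params = params, config = config, seed = seed, extra = extra,
               package_version = as.character(utils::packageVersion("fmricrnn"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$params, "crnn_params"), inherits(ck$config, "crnn_config"))
  ck
}
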