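# Training harness: Adam on the cross-entropy loss, subject-disjoint
# train/validation sets, best-checkpoint retention by validation accuracy,
# early stopping on a validation plateau; evaluation metrics and
# subject-wise k-fold cross-validation.

#' Training configuration
#'
#' @param learning_rate Adam initial learning rate (default 0.001).
#' @param batch_size Samples per optimization step (default 8).
#' @param max_epochs Upper bound on epochs (default 100).
#' @param patience Epochs without validation-accuracy improvement before
#'   stopping (default 10).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8L,
                         max_epochs = 100L, patience = 10L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  paths <- trainable_paths(params)
  list(t = 0L,
       m = lapply(paths, function(p) {
         v <- get_path(params, p)
         if (is.null(dim(v))) numeric(length(v)) else array(0, dim(v))
       }),
       v = lapply(paths, function(p) {
         v <- get_path(params, p)
         if (is.null(dim(v))) numeric(length(v)) else array(0, dim(v))
       }),
       paths = paths)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  lr_t <- cfg$learning_rate *
    sqrt(1 - cfg$beta2^state$t) / (1 - cfg$beta1^state$t)
  for (j in seq_along(state$paths)) {
    p <- state$paths[[j]]
    g <- get_path(grads, p)
    state$m[[j]] <- cfg$beta1 * state$m[[j]] + (1 - cfg$beta1) * g
    state$v[[j]] <- cfg$beta2 * state$v[[j]] + (1 - cfg$beta2) * g * g
    upd <- lr_t * state$m[[j]] / (sqrt(state$v[[j]]) + cfg$epsilon)
    params <- set_path(params, p, get_path(params, p) - upd)
  }
  list(params = params, state = state)
}

set_moving <- function(params, moving) {
  for (i in seq_along(moving)) {
    if (is.null(moving[[i]])) next
    params$conv[[i]]$mov_mean <- moving[[i]]$mov_mean
    params$conv[[i]]$mov_var <- moving[[i]]$mov_var
  }
  params
}

#' Predict class probabilities for a sample set
#'
#' Inference mode: batch norm uses moving statistics, dropout is off.
#'
#' @param params A `crnn_params`.
#' @param config A [crnn_config()].
#' @param set A [sample_set()].
#' @param batch_size Frames batched per forward pass.
#' @return List with `probs` (`[N, K]`) and `preds` (integer labels 0..K-1).
#' @export
crnn_predict <- function(params, config, set, batch_size = 16L) {
  n <- length(set)
  probs <- matrix(0, n, config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- crnn_forward(set$x[i:j], params, config, training = FALSE)
    probs[i:j, ] <- fw$probs
    i <- j + 1L
  }
  list(probs = probs, preds = max.col(probs) - 1L)
}

#' Train the CRNN
#'
#' Minimizes the cross-entropy loss with Adam, evaluating validation
#' accuracy after every epoch. The parameters with the best validation
#' accuracy (ties broken by lower validation loss) are retained; training
#' stops after `patience` epochs without improvement or at `max_epochs`.
#' Refuses to run if any subject appears in both the training and
#' validation sets.
#'
#' @param train_set,val_set Subject-disjoint [sample_set()]s.
#' @param model_config A [crnn_config()].
#' @param config A [train_config()].
#' @param params Optional initial `crnn_params` (default: fresh
#'   Glorot-initialized from the training seed).
#' @param verbose Print one line per epoch.
#' @return List of class `crnn_fit` with `params` (best checkpoint),
#'   `history` (per-epoch data frame), `best_epoch`, `model_config` and
#'   `train_config`.
#' @export
train <- function(train_set, val_set, model_config, config = train_config(),
                  params = NULL, verbose = FALSE) {
  stopifnot(length(train_set) > 0, length(val_set) > 0)
  leaked <- intersect(unique(train_set$subject), unique(val_set$subject))
  if (length(leaked)) {
    stop("subject leakage between train and validation sets: ",
         paste(leaked, collapse = ", "))
  }
  with_seed(config$seed, {
    if (is.null(params)) params <- init_crnn_params(model_config)
    opt <- adam_init(params)
    n <- length(train_set)
    best <- list(acc = -Inf, loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    hist <- list()
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      i <- 1L
      while (i <= n) {
        idx <- ord[i:min(i + config$batch_size - 1L, n)]
        r <- crnn_loss_grads(train_set$x[idx], train_set$y[idx], params,
                             model_config, training = TRUE)
        params <- set_moving(params, r$moving)
        st <- adam_step(params, r$grads, opt, config)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + r$loss * length(idx)
        ep_correct <- ep_correct + sum(r$preds == train_set$y[idx])
        i <- i + config$batch_size
      }
      vp <- crnn_predict(params, model_config, val_set)
      Yv <- matrix(0, length(val_set), model_config$n_classes)
      Yv[cbind(seq_len(length(val_set)), val_set$y + 1L)] <- 1
      # recompute logits-based loss from probs (probs are softmax outputs)
      val_loss <- -mean(log(pmax(vp$probs[cbind(seq_len(length(val_set)),
                                                val_set$y + 1L)], 1e-12)))
      val_acc <- mean(vp$preds == val_set$y)
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val_loss, val_acc = val_acc)
      if (verbose) {
        message(sprintf(
          "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          epoch, ep_loss / n, ep_correct / n, val_loss, val_acc))
      }
      if (val_acc > best$acc ||
          (val_acc == best$acc && val_loss < best$loss)) {
        improved <- val_acc > best$acc
        best <- list(acc = val_acc, loss = val_loss, params = params,
                     epoch = epoch)
        stall <- if (improved) 0L else stall + 1L
      } else {
        stall <- stall + 1L
      }
      if (stall >= config$patience) break
    }
    structure(list(params = best$params, history = do.call(rbind, hist),
                   best_epoch = best$epoch, best_val_acc = best$acc,
                   model_config = model_config, train_config = config),
              class = "crnn_fit")
  })
}

#' @export
print.crnn_fit <- function(x, ...) {
  cat(sprintf("<crnn_fit> %d epoch(s), best epoch %d (val accuracy %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_val_acc))
  invisible(x)
}

#' Classification metrics for a labelled sample set
#'
#' Accuracy, macro-averaged precision / recall / F1 and the full confusion
#' matrix (rows = true class, columns = predicted class). Classes with no
#' predicted (or true) instances contribute 0 to the macro averages.
#'
#' @param model A `crnn_fit` or `crnn_params`.
#' @param set A [sample_set()].
#' @param config Required [crnn_config()] when `model` is bare parameters.
#' @return Object of class `metrics_report`.
#' @export
evaluate <- function(model, set, config = NULL) {
  stopifnot(length(set) > 0)
  if (inherits(model, "crnn_fit")) {
    config <- model$model_config
    model <- model$params
  }
  pr <- crnn_predict(model, config, set)
  metrics_from_predictions(set$y, pr$preds, config$n_classes)
}

#' Metrics from true and predicted labels
#'
#' @param y_true,y_pred Integer labels 0..K-1.
#' @param n_classes Number of classes K.
#' @return Object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1` (macro averages), `confusion` (K x K count
#'   matrix) and `per_class` data frame.
#' @export
metrics_from_predictions <- function(y_true, y_pred, n_classes = 7L) {
  stopifnot(length(y_true) == length(y_pred))
  lv <- 0:(n_classes - 1L)
  confusion <- table(factor(y_true, levels = lv),
                     factor(y_pred, levels = lv))
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(true = lv, predicted = lv))
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = sum(tp) / sum(confusion),
    precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    confusion = confusion,
    per_class = data.frame(class = lv, support = support,
                           precision = prec, recall = rec, f1 = f1)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.4f | macro precision %.4f recall %.4f F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Subject-wise k-fold cross-validation
#'
#' Builds folds with [make_cv_folds()] (every subject in exactly one test
#' partition), trains one model per fold and reports per-fold metrics plus
#' their mean and standard deviation.
#'
#' @param dataset A [sample_set()] covering all subjects.
#' @param model_config A [crnn_config()].
#' @param config A [train_config()]; fold f trains with seed
#'   `config$seed + f`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param verbose Print per-fold progress.
#' @return Object of class `cv_report` with `folds` (list of
#'   `metrics_report`), `mean`, `sd` and a formatted `summary` string per
#'   metric ("xx.xx% ± y.yy%").
#' @export
cross_validate <- function(dataset, model_config, config = train_config(),
                           k = 10L, seed = config$seed, verbose = FALSE) {
  folds <- make_cv_folds(unique(dataset$subject), k = k, seed = seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    sp <- folds[[f]]
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train(subset_subjects(dataset, sp$train_subjects),
                 subset_subjects(dataset, sp$val_subjects),
                 model_config, cfg_f, verbose = verbose)
    reports[[f]] <- evaluate(fit, subset_subjects(dataset, sp$test_subjects))
    if (verbose) {
      message(sprintf("fold %d/%d: test accuracy %.3f", f, k,
                      reports[[f]]$accuracy))
    }
  }
  vals <- sapply(reports, function(r) {
    c(accuracy = r$accuracy, precision = r$precision,
      recall = r$recall, f1 = r$f1)
  })
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, sd)
  structure(list(folds = reports, mean = mu, sd = sdv,
                 summary = sprintf("%.2f%% ± %.2f%%",
                                   100 * mu, 100 * sdv) |>
                   setNames(names(mu))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds\n", length(x$folds)))
  for (nm in names(x$summary)) cat(sprintf("  %-9s %s\n", nm, x$summary[nm]))
  invisible(x)
}
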