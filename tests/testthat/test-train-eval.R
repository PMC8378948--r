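test_that("metrics agree with a brute-force confusion computation", {
  set.seed(51)
  for (r in 1:3) {
    y <- sample(0:6, 300, replace = TRUE)
    p <- sample(0:6, 300, replace = TRUE)
    m <- metrics_from_predictions(y, p, 7)
    # brute force, independent of the implementation
    cm <- matrix(0L, 7, 7)
    for (i in seq_along(y)) cm[y[i] + 1, p[i] + 1] <- cm[y[i] + 1, p[i] + 1] + 1L
    expect_identical(unname(m$confusion), cm)
    expect_equal(m$accuracy, sum(diag(cm)) / 300)
    prec <- rec <- f1 <- numeric(7)
    for (k in 1:7) {
      tp <- cm[k, k]
      prec[k] <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
      rec[k] <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
      f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    }
    expect_equal(m$precision, mean(prec))
    expect_equal(m$recall, mean(rec))
    expect_equal(m$f1, mean(f1))
    expect_identical(unname(rowSums(m$confusion)),
                     as.numeric(table(factor(y, levels = 0:6))))
  }
})

test_that("perfect predictions give unit metrics and a diagonal confusion matrix", {
  y <- rep(0:6, each = 10)
  m <- metrics_from_predictions(y, y, 7)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_true(all(m$confusion[upper.tri(m$confusion)] == 0))
  expect_true(all(m$confusion[lower.tri(m$confusion)] == 0))
  expect_true(all(diag(m$confusion) == 10))
})

test_that("a uniform random predictor on balanced classes sits near chance", {
  set.seed(52)
  y <- rep(0:6, each = 100)
  p <- sample(0:6, 700, replace = TRUE)
  acc <- metrics_from_predictions(y, p, 7)$accuracy
  se <- sqrt((1 / 7) * (6 / 7) / 700)
  expect_lt(abs(acc - 1 / 7), 3 * se)
})

test_that("the binary toy table gives precision = recall = F1 = 0.75", {
  # TP=3, FP=1, FN=1, TN=5 for class 1
  y <- c(rep(1, 4), rep(0, 6))
  p <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- metrics_from_predictions(y, p, 2)
  cls1 <- m$per_class[m$per_class$class == 1, ]
  expect_equal(cls1$precision, 0.75)
  expect_equal(cls1$recall, 0.75)
  expect_equal(cls1$f1, 0.75)
})

test_that("training refuses subject leakage between train and validation", {
  cfg <- tiny_config()
  xs <- tiny_samples(6, cfg, seed = 3)
  tr <- sample_set(xs[1:4], c(0L, 1L, 2L, 0L), rep(c("a", "b"), 2))
  va <- sample_set(xs[5:6], c(1L, 2L), c("b", "c"))
  expect_error(train(tr, va, cfg, train_config(max_epochs = 1)), "leakage")
})

test_that("the model overfits a tiny fixed set and training is seed-deterministic", {
  cfg <- tiny_config()
  xs <- tiny_samples(6, cfg, seed = 13)
  tr <- sample_set(xs, rep(0:2, 2), rep("a", 6))
  va <- sample_set(tiny_samples(3, cfg, seed = 14), 0:2, rep("b", 3))
  tc <- train_config(learning_rate = 0.02, batch_size = 2, max_epochs = 60,
                     patience = 60, seed = 2)
  fit <- train(tr, va, cfg, tc)
  h <- fit$history
  # smoothed loss decreases to near zero on the memorized set
  first <- mean(head(h$train_loss, 3))
  last <- mean(tail(h$train_loss, 3))
  expect_lt(last, 0.2)
  expect_lt(last, first / 3)
  fit2 <- train(tr, va, cfg, tc)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("two-fold cross-validation partitions subjects and averages metrics", {
  cfg <- tiny_config()
  set.seed(61)
  subs <- rep(c("a", "b", "c", "d"), each = 6)
  xs <- tiny_samples(24, cfg, seed = 15)
  ds <- sample_set(xs, rep_len(0:2, 24), subs)
  cv <- cross_validate(ds, cfg, train_config(max_epochs = 2, seed = 3), k = 2)
  expect_length(cv$folds, 2L)
  tested <- unlist(lapply(1:2, function(f) {
    # every sample of the fold's report comes from held-out subjects
    sum(cv$folds[[f]]$confusion)
  }))
  expect_identical(as.integer(tested), c(12L, 12L))  # 2 test subjects x 6 samples
  expect_equal(unname(cv$mean["accuracy"]),
               mean(c(cv$folds[[1]]$accuracy, cv$folds[[2]]$accuracy)))
  expect_match(cv$summary["accuracy"], "^\\d+\\.\\d{2}% ± \\d+\\.\\d{2}%$")
})

test_that("checkpoints round-trip parameters, config and seed", {
  cfg <- tiny_config()
  p <- init_crnn_params(cfg, seed = 77)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(p, cfg, path, seed = 77, extra = list(note = "t"))
  ck <- load_checkpoint(path)
  expect_identical(ck$params, p)
  expect_identical(ck$config$input_shape, cfg$input_shape)
  expect_identical(ck$seed, 77)
})
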