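test_that("block frame counts reproduce the published table for all seven conditions", {
  tab <- hcp_conditions()
  frames <- vapply(tab$duration_s, compute_block_frames, 1L,
                   tr_s = 0.72, post_window_s = 8)
  expect_identical(frames, c(36L, 50L, 44L, 28L, 33L, 43L, 49L))
})

test_that("block frame rounding is to nearest, half away from zero", {
  # 27.78 rounds up (excludes floor), 36.11 rounds down (excludes ceiling)
  expect_identical(compute_block_frames(12, 0.72, 8), 28L)
  expect_identical(compute_block_frames(18, 0.72, 8), 36L)
  expect_identical(compute_block_frames(28, 0.72, 8), 50L)  # exact division
  expect_error(compute_block_frames(0, 0.72, 8), "positive")
  expect_error(compute_block_frames(18, -1, 8), "positive")
})

test_that("spatial crop takes a contiguous centered sub-box of the standard grid", {
  vol <- array(seq_len(91 * 109 * 91), c(91, 109, 91))
  out <- crop_spatial(vol)
  expect_identical(dim(out), c(78L, 93L, 76L))
  expect_identical(out, vol[7:84, 9:101, 8:83])
  # 4D: time axis untouched
  run4 <- array(rnorm(20 * 22 * 20 * 3), c(20, 22, 20, 3))
  m <- list(lower = c(1L, 2L, 1L), upper = c(2L, 2L, 2L))
  out4 <- crop_spatial(run4, margins = m)
  expect_identical(dim(out4), c(17L, 18L, 17L, 3L))
  expect_identical(out4[, , , 2], run4[2:18, 3:20, 2:18, 2])
  # zero-margin crop is the identity
  z <- list(lower = c(0L, 0L, 0L), upper = c(0L, 0L, 0L))
  expect_identical(crop_spatial(out, margins = z), out)
  expect_error(crop_spatial(array(0, c(10, 10, 10))), "91x109x91")
})

test_that("scaled crop margins reproduce the canonical crop and shrink proportionally", {
  m <- scaled_crop_margins(c(91, 109, 91))
  expect_identical(91L - m$lower[1] - m$upper[1], 78L)
  expect_identical(109L - m$lower[2] - m$upper[2], 93L)
  expect_identical(91L - m$lower[3] - m$upper[3], 76L)
  r <- scaled_crop_margins(c(24, 28, 24))
  expect_identical(c(24, 28, 24) - r$lower - r$upper, c(20, 24, 20))
})

test_that("block clips are taken at the rounded onset frame and bounds are enforced", {
  sp <- c(24L, 28L, 24L)
  data <- array(rep(0:39, each = prod(sp)), c(sp, 40))  # frame f holds value f
  run <- raw_run(data, tr_s = 0.72, subject_id = "s1")
  m <- scaled_crop_margins(sp)
  clip <- extract_block_clip(run, onset_s = 7.2, n_frames = 10, margins = m)
  expect_identical(clip$onset_frame, 10L)  # 7.2 / 0.72 exactly
  expect_identical(dim(clip$data), c(20L, 24L, 20L, 10L))
  expect_true(all(clip$data[, , , 1] == 10))
  clip0 <- extract_block_clip(run, 0, 36, margins = m)
  expect_identical(clip0$onset_frame, 0L)
  expect_true(all(clip0$data[, , , 36] == 35))
  expect_error(extract_block_clip(run, 7.2, 36, margins = m), "out of range")
})

test_that("window starts are uniform over the valid range and seeded draws repeat", {
  clip <- ramp_clip(n_frames = 36)
  ws <- sample_windows(clip, window = 21, n_draws = 10000, seed = 4)
  starts <- attr(ws, "starts")
  expect_true(all(starts >= 0 & starts <= 15))
  p <- chisq.test(table(factor(starts, levels = 0:15)))$p.value
  expect_gt(p, 0.01)
  ws2 <- sample_windows(clip, window = 21, n_draws = 10000, seed = 4)
  expect_identical(attr(ws2, "starts"), starts)
  # a 21-frame clip admits exactly one window: the clip itself
  short <- ramp_clip(n_frames = 21)
  one <- sample_windows(short, n_draws = 3, seed = 1)
  expect_true(all(vapply(one, function(w) identical(w, short$data), TRUE)))
  expect_error(sample_windows(ramp_clip(n_frames = 20), n_draws = 1),
               "too short")
})

test_that("balanced augmentation yields the target count per task, spread over blocks", {
  blocks <- c(Emotion = 2, Gambling = 2, Language = 4, Motor = 2,
              Relational = 3, Social = 2, WM = 1)
  frames <- c(36, 50, 44, 28, 33, 43, 49)
  clips <- lapply(seq_along(blocks), function(i) {
    lapply(seq_len(blocks[i]), function(b) ramp_clip(frames[i], label = i - 1L))
  })
  names(clips) <- names(blocks)
  recs <- balance_to_target(clips, target = 12, seed = 2)
  expect_length(recs, 84L)  # 12 x 7
  tasks <- vapply(recs, `[[`, "", "task")
  expect_true(all(table(tasks) == 12))
  # per-block allocation is as even as possible
  lang <- vapply(recs[tasks == "Language"], `[[`, 1, "block")
  expect_true(all(table(lang) == 3))   # 12 / 4 blocks
  wm <- vapply(recs[tasks == "WM"], `[[`, 1, "block")
  expect_true(all(wm == 1))            # single block supplies all 12
  rel <- sort(as.integer(table(vapply(recs[tasks == "Relational"], `[[`, 1, "block"))))
  expect_identical(rel, c(4L, 4L, 4L))
  one <- balance_to_target(clips, target = 1, seed = 2)
  expect_length(one, 7L)
  expect_error(balance_to_target(c(clips, list(Extra = list())), target = 12),
               "missing task")
})

test_that("inter-frame differencing gives 20 non-negative frames", {
  sp <- c(3, 4, 3)
  const <- array(5, c(sp, 21))
  expect_true(all(frame_difference(const) == 0))
  ramp <- array(rep(0:20, each = prod(sp)), c(sp, 21))
  d <- frame_difference(ramp)
  expect_identical(dim(d), c(3L, 4L, 3L, 20L))
  expect_true(all(d == 1))
  expect_error(frame_difference(array(0, c(sp, 20))), "21 frames")
})

test_that("max normalization scales the global maximum to 1 and guards zeros", {
  sp <- c(3, 4, 3)
  x <- array(runif(prod(sp) * 20, 0, 4), c(sp, 20))
  x[2, 2, 2, 5] <- 4
  out <- normalize_sample(x)
  expect_identical(dim(out), c(20L, 3L, 4L, 3L, 1L))
  expect_equal(max(out), 1)
  expect_equal(out[5, 2, 2, 2, 1], 1)
  expect_equal(as.numeric(out[7, 1, 3, 2, 1]), x[1, 3, 2, 7] / 4)
  expect_warning(z <- normalize_sample(array(0, c(sp, 20))), "all-zero")
  expect_true(all(z == 0))
  expect_error(normalize_sample(array(-1, c(sp, 20))), "non-negative")
})

test_that("preprocessing is invariant to rescaling the raw run", {
  sp <- c(24L, 28L, 24L)
  m <- scaled_crop_margins(sp)
  set.seed(9)
  data <- array(runif(prod(sp) * 50, 90, 110), c(sp, 50))
  run1 <- raw_run(data, subject_id = "s1")
  run3 <- raw_run(3.7 * data, subject_id = "s1")
  spec <- task_condition_spec("Emotion", "Fear", 18, c(0, 7.2))
  s1 <- preprocess_subject(list(Emotion = run1), list(Emotion = spec),
                           target = 4, margins = m, seed = 5)
  s3 <- preprocess_subject(list(Emotion = run3), list(Emotion = spec),
                           target = 4, margins = m, seed = 5)
  expect_identical(s1$x, s3$x)
})

test_that("the full per-subject pipeline emits the expected count and shape", {
  sp <- c(24L, 28L, 24L)
  m <- scaled_crop_margins(sp)
  set.seed(10)
  specs <- default_task_specs()[c("Emotion", "Motor")]
  runs <- lapply(specs, function(s) {
    nf <- compute_block_frames(s$condition_duration_s)
    tmax <- round(max(s$onsets_s) / 0.72) + nf + 5
    raw_run(array(runif(prod(sp) * tmax, 90, 110), c(sp, tmax)),
            subject_id = "s1")
  })
  out <- preprocess_subject(runs, specs, target = 12, margins = m, seed = 1)
  expect_length(out, 24L)  # 12 per task
  expect_true(all(vapply(out$x, function(a) identical(dim(a), c(20L, 20L, 24L, 20L, 1L)), TRUE)))
  expect_true(all(vapply(out$x, max, 1) <= 1))
  expect_true(all(vapply(out$x, min, 1) >= 0))
  expect_identical(sort(unique(out$y)), c(0L, 3L))
})

test_that("subject splits are disjoint and folds partition the test sets", {
  ids <- sprintf("sub-%02d", 1:20)
  sp <- split_subjects(ids, seed = 3)
  expect_length(sp$train_subjects, 16L)
  expect_length(sp$val_subjects, 2L)
  expect_length(sp$test_subjects, 2L)
  expect_length(intersect(sp$train_subjects, sp$val_subjects), 0L)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0L)
  expect_length(intersect(sp$val_subjects, sp$test_subjects), 0L)
  expect_setequal(c(sp$train_subjects, sp$val_subjects, sp$test_subjects), ids)

  folds <- make_cv_folds(ids, k = 10, seed = 7)
  expect_length(folds, 10L)
  test_union <- unlist(lapply(folds, `[[`, "test_subjects"))
  expect_length(test_union, 20L)        # no repeats
  expect_setequal(test_union, ids)      # full coverage
  for (f in folds) {
    expect_length(intersect(f$train_subjects, f$test_subjects), 0L)
    expect_length(intersect(f$train_subjects, f$val_subjects), 0L)
    expect_length(intersect(f$val_subjects, f$test_subjects), 0L)
  }
  single <- make_cv_folds(sprintf("s%d", 1:10), k = 10, seed = 1)
  expect_true(all(vapply(single, function(f) length(f$test_subjects), 1L) == 1L))
  expect_error(make_cv_folds(sprintf("s%d", 1:5), k = 10), "at least")
})
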