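# Block-design preprocessing: raw 4D runs + condition timing -> balanced,
# normalized, 20-frame model-ready samples and subject-level splits.

# Round half away from zero (27.78 -> 28, 36.11 -> 36, 50.0 -> 50).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Number of frames spanned by one task block plus the hemodynamic tail
#'
#' A block sample covers the stimulus block itself plus a post-stimulus
#' window (8 s by default) so that the delayed hemodynamic response is
#' captured: `frames = round((duration_s + post_window_s) / tr_s)`, rounding
#' half away from zero.
#'
#' @param duration_s Block duration in seconds (> 0).
#' @param tr_s Repetition time in seconds (default 0.72).
#' @param post_window_s Post-stimulus window in seconds (default 8).
#' @return Integer frame count.
#' @export
#' @examples
#' compute_block_frames(18)   # Fear   -> 36
#' compute_block_frames(12)   # LeftHand -> 28
compute_block_frames <- function(duration_s, tr_s = 0.72, post_window_s = 8) {
  if (!is.numeric(duration_s) || any(duration_s <= 0)) {
    stop("duration_s must be positive")
  }
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be positive")
  if (post_window_s < 0) stop("post_window_s must be non-negative")
  as.integer(round_half_away((duration_s + post_window_s) / tr_s))
}

# Canonical MNI-space crop: 91x109x91 -> 78x93x76, removing peripheral
# black borders symmetrically (leading margins 6, 8, 7).
full_spatial_shape <- c(91L, 109L, 91L)
canonical_crop <- list(lower = c(6L, 8L, 7L), upper = c(7L, 8L, 8L))

#' Crop margins scaled proportionally for a reduced spatial grid
#'
#' The canonical crop removes (6, 8, 7) voxels from the low side and
#' (7, 8, 8) from the high side of a 91 x 109 x 91 volume. For reduced-size
#' simulated volumes the same fractions are removed, rounded to voxels.
#'
#' @param spatial_shape Integer length-3 spatial shape.
#' @return List with integer vectors `lower` and `upper`.
#' @export
scaled_crop_margins <- function(spatial_shape) {
  stopifnot(length(spatial_shape) == 3, all(spatial_shape >= 4))
  lower <- as.integer(round(canonical_crop$lower * spatial_shape / full_spatial_shape))
  upper <- as.integer(round(canonical_crop$upper * spatial_shape / full_spatial_shape))
  list(lower = lower, upper = upper)
}

#' Crop the spatial black borders of a volume or run
#'
#' Removes a fixed margin on each side of each spatial axis. For the
#' standard 91 x 109 x 91 MNI grid the default margins give 78 x 93 x 76;
#' any time axis is untouched.
#'
#' @param volume Rank-3 `[X, Y, Z]` or rank-4 `[X, Y, Z, T]` array.
#' @param margins `NULL` (requires the standard 91 x 109 x 91 grid) or a
#'   list with `lower`/`upper` integer margins, e.g. from
#'   [scaled_crop_margins()].
#' @return The cropped array; spatial shape shrinks by `lower + upper`.
#' @export
crop_spatial <- function(volume, margins = NULL) {
  d <- dim(volume)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("volume must be a rank-3 or rank-4 array")
  }
  sp <- d[1:3]
  if (is.null(margins)) {
    if (!all(sp == full_spatial_shape)) {
      stop(sprintf(
        "spatial shape is %s; expected 91x109x91 (pass margins= for reduced grids)",
        paste(sp, collapse = "x")))
    }
    margins <- canonical_crop
  }
  lo <- as.integer(margins$lower)
  hi <- as.integer(margins$upper)
  stopifnot(length(lo) == 3, length(hi) == 3, all(lo >= 0), all(hi >= 0))
  if (any(sp - lo - hi < 1)) stop("margins leave no voxels on some axis")
  ix <- lapply(1:3, function(a) (lo[a] + 1L):(sp[a] - hi[a]))
  if (length(d) == 3L) {
    volume[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    volume[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  }
}

#' A raw 4D BOLD run
#'
#' @param data Rank-4 array `[X, Y, Z, T]` of BOLD intensities.
#' @param tr_s Repetition time in seconds.
#' @param subject_id Subject identifier.
#' @return Object of class `raw_run`.
#' @export
raw_run <- function(data, tr_s = 0.72, subject_id = "sub-01") {
  d <- dim(data)
  if (is.null(d) || length(d) != 4L) stop("run data must be a rank-4 [X,Y,Z,T] array")
  if (!all(is.finite(data))) stop("run data contains non-finite intensities")
  if (tr_s <= 0) stop("tr_s must be positive")
  structure(list(data = data, tr_s = tr_s, subject_id = subject_id),
            class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_run> subject %s: %dx%dx%d voxels, %d frames, TR %.2f s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Extract one task block (plus hemodynamic tail) from a run
#'
#' The onset is converted to a frame index by `round(onset_s / tr_s)`
#' (0-based) and `n_frames` consecutive frames are taken, spatially cropped.
#'
#' @param run A [raw_run()].
#' @param onset_s Block onset in seconds.
#' @param n_frames Number of frames, normally from [compute_block_frames()].
#' @param margins Crop margins passed to [crop_spatial()].
#' @param task_name,label Optional task annotation carried on the clip.
#' @return Object of class `block_clip` with `data` `[X', Y', Z', n_frames]`.
#' @export
extract_block_clip <- function(run, onset_s, n_frames, margins = NULL,
                               task_name = NA_character_, label = NA_integer_) {
  stopifnot(inherits(run, "raw_run"), n_frames >= 1)
  f0 <- as.integer(round_half_away(onset_s / run$tr_s))
  T_run <- dim(run$data)[4]
  if (f0 < 0 || f0 + n_frames > T_run) {
    stop(sprintf("block [frame %d, %d) out of range for a %d-frame run",
                 f0, f0 + n_frames, T_run))
  }
  cropped <- crop_spatial(run$data[, , , (f0 + 1L):(f0 + n_frames), drop = FALSE],
                          margins = margins)
  structure(list(data = cropped, subject_id = run$subject_id,
                 task_name = task_name, label = label, onset_frame = f0),
            class = "block_clip")
}

#' Draw random contiguous time windows from a block clip
#'
#' Temporal augmentation: each draw is a window of `window` consecutive
#' frames whose 0-based start index is uniform on `[0, F - window]`, drawn
#' with replacement.
#'
#' @param clip A `block_clip`.
#' @param window Window length in frames (default 21).
#' @param n_draws Number of windows to draw.
#' @param seed Optional integer seed for reproducible draws.
#' @return List of rank-4 arrays `[X', Y', Z', window]`, with the 0-based
#'   start indices in attribute `starts`.
#' @export
sample_windows <- function(clip, window = 21L, n_draws = 1L, seed = NULL) {
  stopifnot(inherits(clip, "block_clip"), n_draws >= 1)
  F_clip <- dim(clip$data)[4]
  if (F_clip < window) {
    stop(sprintf("block too short: %d frames < window %d", F_clip, window))
  }
  starts <- with_seed(seed,
    sample.int(F_clip - window + 1L, n_draws, replace = TRUE) - 1L)
  out <- lapply(starts, function(s) {
    clip$data[, , , (s + 1L):(s + window), drop = FALSE]
  })
  attr(out, "starts") <- starts
  out
}

#' Balanced temporal augmentation to a fixed per-task sample count
#'
#' For one subject, draws exactly `target` windows per task, distributing
#' the draws as evenly as possible over that task's blocks (remainders go
#' to the earliest blocks), so every task contributes the same number of
#' training samples regardless of its block count.
#'
#' @param clips_by_task Named list: task name -> list of `block_clip`s for
#'   one subject.
#' @param target Windows per task (default 12).
#' @param window Window length in frames (default 21).
#' @param seed Optional integer seed.
#' @return List of records, each with fields `data` (window array), `task`,
#'   `label`, `subject_id`, `block` and `start`.
#' @export
balance_to_target <- function(clips_by_task, target = 12L, window = 21L,
                              seed = NULL) {
  stopifnot(is.list(clips_by_task), length(clips_by_task) >= 1, target >= 1)
  empties <- names(clips_by_task)[vapply(clips_by_task, length, 1L) == 0]
  if (length(empties)) {
    stop("missing task blocks for: ", paste(empties, collapse = ", "))
  }
  with_seed(seed, {
    out <- list()
    for (task in names(clips_by_task)) {
      clips <- clips_by_task[[task]]
      nb <- length(clips)
      draws <- rep(target %/% nb, nb) + (seq_len(nb) <= target %% nb)
      for (b in seq_len(nb)) {
        if (draws[b] == 0) next
        ws <- sample_windows(clips[[b]], window = window, n_draws = draws[b])
        starts <- attr(ws, "starts")
        for (j in seq_along(ws)) {
          out[[length(out) + 1L]] <- list(
            data = ws[[j]], task = task, label = clips[[b]]$label,
            subject_id = clips[[b]]$subject_id, block = b,
            start = starts[j])
        }
      }
    }
    out
  })
}

#' Absolute inter-frame difference of a 21-frame window
#'
#' Subtracting consecutive frames and taking the absolute value highlights
#' voxels whose intensity is changing — the signature of an evolving
#' hemodynamic response — and suppresses the static anatomy.
#'
#' @param sample21 Rank-4 array `[X, Y, Z, 21]`.
#' @return Rank-4 array `[X, Y, Z, 20]`, all entries >= 0.
#' @export
frame_difference <- function(sample21) {
  d <- dim(sample21)
  if (is.null(d) || length(d) != 4L || d[4] != 21L) {
    stop("sample21 must be a rank-4 array with exactly 21 frames")
  }
  abs(sample21[, , , 2:21, drop = FALSE] - sample21[, , , 1:20, drop = FALSE])
}

#' Normalize a differenced sample by its global maximum
#'
#' Every voxel of every frame is divided by the single scalar maximum over
#' all 20 frames, so the sample's global maximum becomes exactly 1; a
#' trailing channel axis is appended and time moves to the first axis,
#' giving the model-ready shape `[20, X, Y, Z, 1]`.
#'
#' @param sample20 Rank-4 array `[X, Y, Z, 20]` with non-negative entries.
#' @return Rank-5 array `[20, X, Y, Z, 1]` with values in `[0, 1]`. An
#'   all-zero sample is returned unchanged (zeros) with a warning.
#' @export
normalize_sample <- function(sample20) {
  d <- dim(sample20)
  if (is.null(d) || length(d) != 4L || d[4] != 20L) {
    stop("sample20 must be a rank-4 array with exactly 20 frames")
  }
  if (any(sample20 < 0)) stop("sample20 must be non-negative (run frame_difference first)")
  m <- max(sample20)
  if (m == 0) {
    warning("all-zero sample passed to normalize_sample; returning zeros")
  } else {
    sample20 <- sample20 / m
  }
  out <- aperm(sample20, c(4L, 1L, 2L, 3L))
  dim(out) <- c(20L, d[1], d[2], d[3], 1L)
  out
}

#' Full preprocessing for one subject's runs
#'
#' Applies the whole chain — block-frame calculation, block extraction with
#' spatial crop, balanced 21-frame window augmentation, inter-frame
#' differencing and max normalization — producing `target` model-ready
#' samples per task.
#'
#' @param runs_by_task Named list: task name -> [raw_run()] for one subject.
#' @param specs_by_task Named list of [task_condition_spec()] (defaults to
#'   [default_task_specs()] restricted to the supplied tasks).
#' @param target Samples per task (default 12).
#' @param window Window length (default 21).
#' @param margins Crop margins (`NULL` = canonical full-size crop); pass
#'   [scaled_crop_margins()] output for reduced grids.
#' @param post_window_s Hemodynamic tail in seconds (default 8).
#' @param seed Optional integer seed.
#' @return A [sample_set()].
#' @export
preprocess_subject <- function(runs_by_task, specs_by_task = NULL,
                               target = 12L, window = 21L, margins = NULL,
                               post_window_s = 8, seed = NULL) {
  if (is.null(specs_by_task)) {
    specs_by_task <- default_task_specs()[names(runs_by_task)]
  }
  stopifnot(all(names(runs_by_task) %in% names(specs_by_task)))
  labels <- setNames(hcp_conditions()$label, hcp_conditions()$task)
  clips_by_task <- lapply(names(runs_by_task), function(task) {
    run <- runs_by_task[[task]]
    spec <- specs_by_task[[task]]
    nf <- compute_block_frames(spec$condition_duration_s, run$tr_s, post_window_s)
    lapply(spec$onsets_s, function(on) {
      extract_block_clip(run, on, nf, margins = margins,
                         task_name = task, label = labels[[task]])
    })
  })
  names(clips_by_task) <- names(runs_by_task)
  recs <- balance_to_target(clips_by_task, target = target, window = window,
                            seed = seed)
  x <- lapply(recs, function(r) normalize_sample(frame_difference(r$data)))
  sample_set(x = x,
             y = vapply(recs, function(r) as.integer(r$label), 1L),
             subject = vapply(recs, function(r) r$subject_id, ""))
}

#' A set of model-ready samples
#'
#' @param x List of rank-5 arrays `[20, X, Y, Z, 1]`.
#' @param y Integer class labels 0-6.
#' @param subject Character subject ids, one per sample.
#' @return Object of class `sample_set`.
#' @export
sample_set <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(y) == length(subject))
  structure(list(x = x, y = as.integer(y), subject = as.character(subject)),
            class = "sample_set")
}

#' @export
length.sample_set <- function(x) length(x$y)

#' @export
print.sample_set <- function(x, ...) {
  d <- if (length(x$y)) paste(dim(x$x[[1]]), collapse = "x") else "?"
  cat(sprintf("<sample_set> %d samples [%s], %d subject(s), %d class(es)\n",
              length(x$y), d, length(unique(x$subject)),
              length(unique(x$y))))
  invisible(x)
}

#' Subset a sample set by subject ids
#' @param set A [sample_set()].
#' @param subjects Character vector of subject ids to keep.
#' @return A [sample_set()].
#' @export
subset_subjects <- function(set, subjects) {
  keep <- set$subject %in% subjects
  sample_set(set$x[keep], set$y[keep], set$subject[keep])
}

#' Combine sample sets
#' @param ... `sample_set` objects.
#' @return A single [sample_set()].
#' @export
bind_sample_sets <- function(...) {
  sets <- list(...)
  sample_set(do.call(c, lapply(sets, `[[`, "x")),
             do.call(c, lapply(sets, `[[`, "y")),
             do.call(c, lapply(sets, `[[`, "subject")))
}

#' Subject-wise train/validation/test split
#'
#' Subjects (not samples) are partitioned 80/10/10 so that no person
#' contributes data to more than one partition.
#'
#' @param subject_ids Character vector of distinct subject ids.
#' @param seed Optional integer seed.
#' @param ratios Length-3 proportions for train/val/test (sum to 1).
#' @return Object of class `dataset_split` with `train_subjects`,
#'   `val_subjects`, `test_subjects` and `fold_index`.
#' @export
split_subjects <- function(subject_ids, seed = NULL, ratios = c(0.8, 0.1, 0.1)) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  stopifnot(n >= 3, abs(sum(ratios) - 1) < 1e-8)
  perm <- with_seed(seed, sample(subject_ids))
  n_test <- max(1L, round(n * ratios[3]))
  n_val <- max(1L, round(n * ratios[2]))
  structure(list(
    train_subjects = perm[seq_len(n - n_val - n_test)],
    val_subjects = perm[(n - n_val - n_test + 1L):(n - n_test)],
    test_subjects = perm[(n - n_test + 1L):n],
    fold_index = 0L
  ), class = "dataset_split")
}

#' Subject-wise k-fold cross-validation splits
#'
#' Subjects are shuffled once and divided into `k` near-equal groups; fold
#' `i` uses group `i` as the test set, about a ninth of the remaining
#' subjects (at least one) as the validation set and the rest for
#' training, so across the `k` folds every subject appears in exactly one
#' test partition and each fold approximates the 80/10/10 design.
#'
#' @param subject_ids Character vector of distinct subject ids (>= k).
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return List of `k` `dataset_split` objects (`fold_index` 0..k-1).
#' @export
make_cv_folds <- function(subject_ids, k = 10L, seed = NULL) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (n < k) stop(sprintf("need at least k = %d subjects, got %d", k, n))
  if (k < 2) stop("k must be >= 2")
  perm <- with_seed(seed, sample(subject_ids))
  groups <- split(perm, sort(rep_len(seq_len(k), n)))
  lapply(seq_len(k), function(i) {
    rest <- unlist(groups[-i], use.names = FALSE)
    n_val <- min(max(1L, round(length(rest) / 9)), length(rest) - 1L)
    structure(list(
      train_subjects = rest[-seq_len(n_val)],
      val_subjects = rest[seq_len(n_val)],
      test_subjects = groups[[i]],
      fold_index = i - 1L
    ), class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> fold %d: %d train / %d val / %d test subjects\n",
              x$fold_index, length(x$train_subjects), length(x$val_subjects),
              length(x$test_subjects)))
  invisible(x)
}
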