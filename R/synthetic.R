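# Synthetic task-fMRI generator: multi-subject 4D runs with
# condition-specific HRF-convolved block activations in distinct spherical
# ROIs over a noisy baseline, at full (91x109x91) or reduced spatial size.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak ~5 s, undershoot ~15 s),
#' normalized so the peak response equals 1. This delayed, smooth response
#' is why block samples extend 8 s past the stimulus block.
#'
#' @param t Time in seconds (>= 0); vectorized.
#' @return Unitless response values with maximum 1 at the peak.
#' @export
#' @examples
#' hrf(0)            # 0
#' hrf(5)            # ~1 (peak)
hrf <- function(t) {
  stopifnot(all(t >= 0))
  raw <- function(x) {
    stats::dgamma(x, shape = 6, rate = 1) -
      stats::dgamma(x, shape = 16, rate = 1) / 6
  }
  if (is.null(the_hrf_cache$peak)) {
    grid <- seq(0, 32, by = 0.01)
    the_hrf_cache$peak <- max(raw(grid))
  }
  raw(t) / the_hrf_cache$peak
}

#' Simulation configuration
#'
#' Defaults emulate the decoding study's data model: TR 0.72 s, the seven
#' published conditions with their block counts, a BOLD-like baseline of
#' 100 with block activations of 3% of baseline and unit Gaussian noise.
#' The reduced spatial mode (e.g. 24 x 28 x 24) keeps every temporal
#' property and scales the spatial crop proportionally.
#'
#' @param spatial_shape Length-3 voxel grid (default full `c(91, 109, 91)`).
#' @param tr_s Repetition time in seconds (default 0.72).
#' @param n_subjects Number of subjects.
#' @param tasks Named list of [task_condition_spec()] (default
#'   [default_task_specs()]).
#' @param roi_radius ROI sphere radius in voxels; `NULL` picks
#'   `max(2, round(min(cropped dims)/8))`.
#' @param effect_amplitude Peak activation as a fraction of baseline
#'   (default 0.03).
#' @param noise_sd Gaussian noise standard deviation in intensity units
#'   (default 1).
#' @param drift_amplitude Amplitude of a slow sinusoidal drift (default 0.5).
#' @param drift_period_s Drift period in seconds (default 120).
#' @param baseline Baseline intensity (default 100).
#' @param seed Base seed; subject/task runs derive their own sub-seeds.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(spatial_shape = c(91L, 109L, 91L), tr_s = 0.72,
                       n_subjects = 10L, tasks = default_task_specs(),
                       roi_radius = NULL, effect_amplitude = 0.03,
                       noise_sd = 1, drift_amplitude = 0.5,
                       drift_period_s = 120, baseline = 100, seed = 1L) {
  stopifnot(length(spatial_shape) == 3, all(spatial_shape >= 8),
            tr_s > 0, n_subjects >= 1, effect_amplitude >= 0,
            noise_sd >= 0, drift_amplitude >= 0, baseline > 0)
  margins <- scaled_crop_margins(spatial_shape)
  cropped <- as.integer(spatial_shape) - margins$lower - margins$upper
  if (is.null(roi_radius)) roi_radius <- max(2L, round(min(cropped) / 8))
  if (2 * roi_radius + 1 > min(cropped)) {
    stop("roi_radius too large for the cropped volume")
  }
  structure(list(spatial_shape = as.integer(spatial_shape), tr_s = tr_s,
                 n_subjects = as.integer(n_subjects), tasks = tasks,
                 roi_radius = as.integer(roi_radius),
                 effect_amplitude = effect_amplitude, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s, baseline = baseline,
                 seed = as.integer(seed), crop_margins = margins),
            class = "sim_config")
}

# Deterministic distinct ROI centers: 7 points of a lattice inside the
# cropped box, mapped back to full-volume coordinates.
roi_centers <- function(config) {
  lo <- config$crop_margins$lower
  hi <- config$spatial_shape - config$crop_margins$upper
  frac <- rbind(c(.30, .30, .30), c(.70, .30, .30), c(.30, .70, .30),
                c(.30, .30, .70), c(.70, .70, .30), c(.70, .30, .70),
                c(.30, .70, .70))
  centers <- t(apply(frac, 1, function(f) round(lo + f * (hi - lo))))
  rownames(centers) <- names(config$tasks)[seq_len(nrow(centers))]
  centers
}

roi_mask <- function(config, center) {
  d <- config$spatial_shape
  r <- config$roi_radius
  mask <- array(FALSE, d)
  xr <- max(1, center[1] - r):min(d[1], center[1] + r)
  yr <- max(1, center[2] - r):min(d[2], center[2] + r)
  zr <- max(1, center[3] - r):min(d[3], center[3] + r)
  for (z in zr) for (y in yr) for (x in xr) {
    if ((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= r^2) {
      mask[x, y, z] <- TRUE
    }
  }
  mask
}

# HRF-convolved boxcar time course at TR resolution, normalized to peak 1.
block_bold_course <- function(spec, tr_s, n_frames) {
  times <- (seq_len(n_frames) - 1) * tr_s
  box <- numeric(n_frames)
  for (on in spec$onsets_s) {
    box[times >= on & times < on + spec$condition_duration_s] <- 1
  }
  h <- hrf(seq(0, 32, by = tr_s))
  sig <- as.numeric(stats::convolve(box, rev(h), type = "open"))[seq_len(n_frames)]
  m <- max(sig)
  if (m > 0) sig <- sig / m
  sig
}

#' Generate one synthetic task run
#'
#' Baseline + HRF-convolved boxcar activation inside the task's ROI +
#' global sinusoidal drift + i.i.d. Gaussian noise. Bit-identical for a
#' fixed seed.
#'
#' @param subject_id Subject identifier.
#' @param task A [task_condition_spec()]; must be one of `config$tasks`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this run's noise.
#' @return Object of class `sim_run`: a [raw_run()] plus ground truth
#'   (`task_name`, `label`, `roi_mask`, `signal` — the noiseless ROI time
#'   course, zero outside the ROI).
#' @export
generate_run <- function(subject_id, task, config, seed = NULL) {
  stopifnot(inherits(task, "task_condition_spec"), inherits(config, "sim_config"))
  centers <- roi_centers(config)
  if (!task$task_name %in% rownames(centers)) {
    stop("task has no assigned ROI center: ", task$task_name)
  }
  n_block_frames <- compute_block_frames(task$condition_duration_s,
                                         config$tr_s)
  last_onset_frame <- round_half_away(max(task$onsets_s) / config$tr_s)
  n_frames <- as.integer(last_onset_frame + n_block_frames + 6L)
  mask <- roi_mask(config, centers[task$task_name, ])
  course <- block_bold_course(task, config$tr_s, n_frames)
  amp <- config$effect_amplitude * config$baseline
  d <- config$spatial_shape
  data <- with_seed(seed, {
    arr <- array(rnorm(prod(d) * n_frames, mean = config$baseline,
                       sd = config$noise_sd), c(d, n_frames))
    tt <- (seq_len(n_frames) - 1) * config$tr_s
    drift <- config$drift_amplitude * sin(2 * pi * tt / config$drift_period_s)
    nvox <- prod(d)
    midx <- which(mask)
    for (f in seq_len(n_frames)) {
      off <- (f - 1L) * nvox
      arr[off + seq_len(nvox)] <- arr[off + seq_len(nvox)] + drift[f]
      if (amp > 0) arr[off + midx] <- arr[off + midx] + amp * course[f]
    }
    arr
  })
  run <- raw_run(data, tr_s = config$tr_s, subject_id = subject_id)
  structure(list(run = run, task_name = task$task_name,
                 label = setNames(hcp_conditions()$label,
                                  hcp_conditions()$task)[[task$task_name]],
                 roi_mask = mask, signal = amp * course,
                 spec = task),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> %s / %s: %d frames, %d ROI voxels\n",
              x$run$subject_id, x$task_name, dim(x$run$data)[4],
              sum(x$roi_mask)))
  invisible(x)
}

#' Generate a full multi-subject synthetic dataset
#'
#' One run per subject per task (7 tasks), with the published condition
#' durations and per-run block counts. With `dir` set, runs are written as
#' NIfTI files with matching 3-column event files, consumable unchanged by
#' the preprocessing module; otherwise runs are returned in memory.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing); NIfTI runs go
#'   to `dir/runs`, event files to `dir/events`.
#' @return If `dir` is `NULL`, a list of per-subject named lists of
#'   `sim_run`s. Otherwise a manifest data frame (one row per run) written
#'   alongside the files as `manifest.json`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- sprintf("sub-%02d", seq_len(config$n_subjects))
  run_seed <- function(s, t) config$seed + 1000L * s + t
  if (is.null(dir)) {
    out <- lapply(seq_along(subjects), function(s) {
      runs <- lapply(seq_along(config$tasks), function(t) {
        generate_run(subjects[s], config$tasks[[t]], config,
                     seed = run_seed(s, t))
      })
      setNames(runs, names(config$tasks))
    })
    return(setNames(out, subjects))
  }
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "events"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seq_along(subjects)) {
    for (t in seq_along(config$tasks)) {
      sr <- generate_run(subjects[s], config$tasks[[t]], config,
                         seed = run_seed(s, t))
      task <- names(config$tasks)[t]
      nii <- file.path(dir, "runs", sprintf("%s_%s.nii.gz", subjects[s], task))
      ev <- file.path(dir, "events", sprintf("%s_%s_events.tsv", subjects[s], task))
      write_nifti(sr$run, nii)
      write_events(sr$spec, ev)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[s], task = task, run_file = nii, event_file = ev,
        n_frames = dim(sr$run$data)[4], seed = run_seed(s, t))
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(
    list(seed = config$seed, spatial_shape = config$spatial_shape,
         tr_s = config$tr_s, effect_amplitude = config$effect_amplitude,
         noise_sd = config$noise_sd, runs = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest
}

#' Preprocess an in-memory synthetic dataset into model-ready samples
#'
#' Convenience wrapper: applies [preprocess_subject()] (with the crop
#' margins implied by the simulation's spatial shape) to every subject of a
#' [generate_dataset()] result.
#'
#' @param sims Result of `generate_dataset(config)` (in-memory form).
#' @param config The [sim_config()] used to generate `sims`.
#' @param target,window,seed Passed to [preprocess_subject()].
#' @return A [sample_set()] covering all subjects.
#' @export
preprocess_dataset <- function(sims, config, target = 12L, window = 21L,
                               seed = NULL) {
  margins <- if (all(config$spatial_shape == full_spatial_shape)) NULL else
    config$crop_margins
  specs <- config$tasks
  sets <- lapply(seq_along(sims), function(s) {
    runs <- lapply(sims[[s]], function(sr) sr$run)
    preprocess_subject(runs, specs, target = target, window = window,
                       margins = margins,
                       seed = if (is.null(seed)) NULL else seed + s)
  })
  do.call(bind_sample_sets, sets)
}
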