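# Shared I/O: NIfTI runs, 3-column event files, the sample container and
# the layered YAML configuration.

#' Read a 4D NIfTI run
#'
#' Accepts `.nii` and `.nii.gz`; the run must be rank 4 with axis order
#' `(X, Y, Z, T)`. The TR is taken from the header's 4th pixdim unless
#' overridden.
#'
#' @param path Path to the NIfTI file.
#' @param subject_id Subject id to attach (default: file name prefix).
#' @param tr_s Repetition time override in seconds (`NULL` = header value).
#' @return A [raw_run()].
#' @export
read_nifti <- function(path, subject_id = NULL, tr_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file ", path, ": ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 4L) {
    stop(sprintf("%s: expected a rank-4 (X,Y,Z,T) volume, got rank %d",
                 path, length(d)))
  }
  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(img)
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 0.72
  }
  if (is.null(subject_id)) {
    subject_id <- sub("[_.].*$", "", basename(path))
  }
  raw_run(array(as.numeric(img), dim = d), tr_s = tr_s,
          subject_id = subject_id)
}

#' Write a run as NIfTI
#'
#' Stored as float32 (sufficient for BOLD dynamic range, half the size);
#' the TR is recorded in the 4th pixdim.
#'
#' @param run A [raw_run()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(run, path) {
  stopifnot(inherits(run, "raw_run"))
  img <- RNifti::asNifti(run$data,
                         reference = list(pixdim = c(-1, 1, 1, 1, run$tr_s,
                                                     0, 0, 0)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-column event file
#'
#' Tab- or space-delimited columns: onset seconds, duration seconds,
#' condition label (the EV convention). All rows must share one duration
#' (one condition per file).
#'
#' @param path Event file path.
#' @param task_name Task the events belong to (default: guessed from the
#'   file name, `<subject>_<task>_events.tsv`).
#' @return A [task_condition_spec()].
#' @export
read_events <- function(path, task_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- read.table(path, header = FALSE,
                   col.names = c("onset", "duration", "label"),
                   stringsAsFactors = FALSE)
  if (nrow(ev) < 1) stop(path, ": empty event file")
  if (length(unique(ev$duration)) != 1) {
    stop(path, ": expected a single condition duration, got several")
  }
  if (is.null(task_name)) {
    parts <- strsplit(sub("_events\\..*$", "", basename(path)), "_")[[1]]
    task_name <- parts[length(parts)]
  }
  task_condition_spec(task_name, ev$label[1], ev$duration[1], ev$onset)
}

#' Write a condition's events as a 3-column file
#'
#' @param spec A [task_condition_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(spec, path) {
  stopifnot(inherits(spec, "task_condition_spec"))
  df <- data.frame(onset = spec$onsets_s,
                   duration = spec$condition_duration_s,
                   label = spec$condition_label)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a preprocessed sample container
#'
#' One container file per split holding the datasets `X` (list of rank-5
#' float sample arrays), `y` (integer labels) and `subject` (ids), plus a
#' JSON sidecar manifest recording provenance (seed, crop margins, window,
#' target, sample count).
#'
#' @param set A [sample_set()].
#' @param path Container path (`.rds`).
#' @param provenance Named list merged into the manifest.
#' @return `save_samples` returns `path` invisibly; `load_samples` returns
#'   the [sample_set()].
#' @export
save_samples <- function(set, path, provenance = list()) {
  stopifnot(inherits(set, "sample_set"))
  saveRDS(list(X = lapply(set$x, function(a) {
    storage.mode(a) <- "double"
    a
  }), y = set$y, subject = set$subject), path)
  manifest <- c(list(n_samples = length(set),
                     sample_shape = if (length(set)) dim(set$x[[1]]) else NULL,
                     classes = sort(unique(set$y)),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                provenance)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_samples
#' @export
load_samples <- function(path) {
  obj <- readRDS(path)
  sample_set(obj$X, obj$y, obj$subject)
}

config_defaults <- function() {
  list(
    model = list(
      conv_kernels = list(c(7, 7, 7), c(3, 3, 3), c(3, 3, 3), c(8, 10, 8)),
      conv_channels = c(32, 64, 64, 64),
      conv_strides = c(2, 2, 2, 1),
      lstm_units = 64, lstm_dropout = 0.2,
      attention_dim = 64, attention_type = "additive",
      dense_units = 64, n_classes = 7,
      input_shape = c(20, 78, 93, 76, 1)),
    train = list(learning_rate = 0.001, batch_size = 8, max_epochs = 100,
                 patience = 10, seed = 1),
    preprocess = list(window = 21, target = 12, post_window_s = 8,
                      crop_margins = NULL),
    simulate = list(spatial_shape = c(91, 109, 91), tr_s = 0.72,
                    n_subjects = 10, effect_amplitude = 0.03, noise_sd = 1,
                    drift_amplitude = 0.5, baseline = 100, seed = 1)
  )
}

merge_section <- function(base, override, path) {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      near <- agrep(key, names(base), max.distance = 0.3, value = TRUE)
      stop(sprintf("unknown config key '%s%s'%s", path, key,
                   if (length(near)) paste0("; did you mean '", near[1], "'?")
                   else ""))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
        is.list(override[[key]])) {
      base[[key]] <- merge_section(base[[key]], override[[key]],
                                   paste0(path, key, "/"))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Layered configuration: defaults < file < overrides
#'
#' Reads a YAML file with sections `model`, `train`, `preprocess` and
#' `simulate`, merged over the published defaults; explicit `overrides`
#' (e.g. parsed CLI flags) win over both. Unknown keys are rejected with
#' the nearest valid key named.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Nested named list with the same section structure.
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    file_cfg <- yaml::read_yaml(path)
    if (length(file_cfg)) cfg <- merge_section(cfg, file_cfg, "")
  }
  if (length(overrides)) cfg <- merge_section(cfg, overrides, "")
  cfg
}

#' Build a [crnn_config()] from a configuration list
#'
#' @param cfg Result of [load_config()] (its `model` section is used).
#' @return A [crnn_config()].
#' @export
crnn_config_from_list <- function(cfg) {
  m <- cfg$model
  blocks <- lapply(seq_along(m$conv_kernels), function(i) {
    conv_block_config(unlist(m$conv_kernels[[i]]), m$conv_channels[i],
                      m$conv_strides[i])
  })
  crnn_config(conv_blocks = blocks, lstm_units = m$lstm_units,
              lstm_dropout = m$lstm_dropout,
              attention_dim = m$attention_dim,
              attention_type = m$attention_type,
              dense_units = m$dense_units, n_classes = m$n_classes,
              input_shape = unlist(m$input_shape))
}
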