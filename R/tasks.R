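#' The seven HCP task conditions used for decoding
#'
#' One condition is selected per task paradigm. Durations are the published
#' block lengths in seconds; `n_blocks` is the number of times that condition
#' occurs within a single subject's run. Tasks are ordered alphabetically and
#' this order defines the integer class labels 0-6 used throughout.
#'
#' @return A data frame with columns `task`, `condition`, `duration_s`,
#'   `n_blocks` and `label` (integer 0-6).
#' @export
#' @examples
#' hcp_conditions()
hcp_conditions <- function() {
  data.frame(
    task = c("Emotion", "Gambling", "Language", "Motor",
             "Relational", "Social", "WM"),
    condition = c("Fear", "Loss", "Story", "LeftHand",
                  "Relation", "Mental", "2bk_places"),
    duration_s = c(18, 28, 24, 12, 16, 23, 27.5),
    n_blocks = c(2L, 2L, 4L, 2L, 3L, 2L, 1L),
    label = 0:6,
    stringsAsFactors = FALSE
  )
}

#' Timing metadata for one condition of one task
#'
#' @param task_name One of the seven task paradigms (see [hcp_conditions()]).
#' @param condition_label Condition name, e.g. `"Fear"`.
#' @param condition_duration_s Block duration in seconds (> 0).
#' @param onsets_s Numeric vector of block onset times in seconds, one entry
#'   per block.
#' @return An object of class `task_condition_spec`.
#' @export
task_condition_spec <- function(task_name, condition_label,
                                condition_duration_s, onsets_s) {
  tasks <- hcp_conditions()$task
  task_name <- match.arg(task_name, tasks)
  if (!is.numeric(condition_duration_s) || length(condition_duration_s) != 1 ||
      condition_duration_s <= 0) {
    stop("condition_duration_s must be a single positive number")
  }
  if (length(onsets_s) < 1 || any(!is.finite(onsets_s)) || any(onsets_s < 0)) {
    stop("onsets_s must contain at least one finite non-negative onset")
  }
  structure(
    list(task_name = task_name,
         condition_label = condition_label,
         condition_duration_s = as.numeric(condition_duration_s),
         onsets_s = as.numeric(onsets_s),
         n_blocks = length(onsets_s)),
    class = "task_condition_spec"
  )
}

#' @export
print.task_condition_spec <- function(x, ...) {
  cat(sprintf("<task_condition_spec> %s / %s: %g s x %d block(s) at %s s\n",
              x$task_name, x$condition_label, x$condition_duration_s,
              x$n_blocks, paste(round(x$onsets_s, 2), collapse = ", ")))
  invisible(x)
}

# Evenly spaced default onsets: a lead-in rest, then blocks separated by a
# rest gap long enough for the 8 s post-stimulus window plus HRF decay.
default_onsets <- function(duration_s, n_blocks, lead_s = 12, gap_s = 14) {
  lead_s + (seq_len(n_blocks) - 1) * (duration_s + gap_s)
}

#' Default condition specs with canonical block timing
#'
#' Builds one [task_condition_spec()] per task using the published durations
#' and per-run block counts, with synthetic evenly spaced onsets (12 s
#' lead-in, 14 s inter-block rest).
#'
#' @return Named list of `task_condition_spec`, one per task.
#' @export
default_task_specs <- function() {
  tab <- hcp_conditions()
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    task_condition_spec(
      task_name = tab$task[i],
      condition_label = tab$condition[i],
      condition_duration_s = tab$duration_s[i],
      onsets_s = default_onsets(tab$duration_s[i], tab$n_blocks[i])
    )
  })
  setNames(specs, tab$task)
}
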