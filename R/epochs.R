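#' Epoched EEG container
#'
#' A lightweight container for epoched multi-channel EEG: a numeric array
#' `[channel, time, trial]` plus the time axis (ms relative to stimulus
#' onset), sampling rate, montage and per-trial condition labels.
#'
#' @param data Numeric array with dims channel x time x trial.
#' @param times Numeric vector of sample times in ms (length = dim 2).
#' @param fs Sampling rate in Hz.
#' @param montage Montage data.frame (one row per channel).
#' @param condition Character vector of per-trial condition labels.
#' @param task Optional task name ("AOB" or "GNG").
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, fs, montage, condition, task = NULL) {
  stopifnot(length(dim(data)) == 3)
  stopifnot(dim(data)[1] == nrow(montage))
  stopifnot(dim(data)[2] == length(times))
  stopifnot(dim(data)[3] == length(condition))
  structure(
    list(data = data, times = times, fs = fs, montage = montage,
         condition = as.character(condition), task = task),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d channels x %d samples (%g..%g ms, %g Hz) x %d trials\n",
    dim(x$data)[1], dim(x$data)[2], min(x$times), max(x$times), x$fs,
    dim(x$data)[3]
  ))
  tb <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Subset epochs by trial index or condition
#'
#' @param x An `eeg_epochs` object.
#' @param trials Integer or logical index over trials, or a character vector
#'   of condition labels.
#' @return A new `eeg_epochs` with the selected trials.
#' @export
subset_epochs <- function(x, trials) {
  if (is.character(trials)) trials <- x$condition %in% trials
  eeg_epochs(x$data[, , trials, drop = FALSE], x$times, x$fs, x$montage,
             x$condition[trials], x$task)
}

#' Number of trials per condition
#' @param x An `eeg_epochs` object.
#' @return Named integer vector.
#' @export
n_trials <- function(x) {
  tb <- table(x$condition)
  stats::setNames(as.integer(tb), names(tb))
}

# indices of post-stimulus samples (t >= 0, half-open convention [0, end))
post_stim_idx <- function(times) which(times >= 0)
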