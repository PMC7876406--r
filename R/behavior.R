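#' Exclude reaction-time outliers (single-pass k-SD rule)
#'
#' Removes every RT farther than `k` standard deviations from the mean,
#' with mean and SD computed once on the full list (no re-iteration). With
#' zero SD nothing is excluded.
#'
#' @param rts Numeric vector of reaction times (ms), length >= 2.
#' @param k SD multiple (default 2.5).
#' @return List: `retained` (numeric), `excluded_fraction` (percent).
#' @export
exclude_rt_outliers <- function(rts, k = 2.5) {
  stopifnot(length(rts) >= 2)
  m <- mean(rts)
  s <- stats::sd(rts)
  if (!is.finite(s) || s == 0) {
    return(list(retained = rts, excluded_fraction = 0))
  }
  keep <- abs(rts - m) <= k * s
  list(retained = rts[keep], excluded_fraction = 100 * mean(!keep))
}

#' Summarize behavioral performance
#'
#' Per-condition percent correct, and RT mean/SD over correct,
#' outlier-excluded responses. NoGo conditions are summarized by percent
#' correct only (correct = withheld response). The recording is valid when
#' the overall percent correct across scoreable trials reaches the 65%
#' minimum.
#'
#' @param record A `behavioral_record` data.frame.
#' @param k Outlier SD multiple for [exclude_rt_outliers()].
#' @param min_correct Validity threshold (proportion).
#' @return A `behavioral_summary` list: `by_condition` (data.frame with
#'   `condition`, `n_trials`, `percent_correct`, `rt_mean`, `rt_sd`,
#'   `excluded_fraction`), `overall_percent_correct`, `valid_recording`.
#' @export
summarize_behavior <- function(record, k = 2.5, min_correct = 0.65) {
  scoreable <- !is.na(record$correct)
  rows <- NULL
  for (cond in unique(record$condition[scoreable])) {
    idx <- which(record$condition == cond & scoreable)
    pc <- 100 * mean(record$correct[idx])
    rt_mean <- rt_sd <- NA_real_
    excl <- NA_real_
    rts <- record$rt_ms[idx][record$correct[idx] & record$responded[idx]]
    rts <- rts[!is.na(rts)]
    if (length(rts) >= 2) {
      ex <- exclude_rt_outliers(rts, k)
      rt_mean <- mean(ex$retained)
      rt_sd <- stats::sd(ex$retained)
      excl <- ex$excluded_fraction
    } else if (length(rts) == 1) {
      rt_mean <- rts
      excl <- 0
    }
    rows <- rbind(rows, data.frame(
      condition = cond, n_trials = length(idx), percent_correct = pc,
      rt_mean = rt_mean, rt_sd = rt_sd, excluded_fraction = excl,
      stringsAsFactors = FALSE
    ))
  }
  overall <- 100 * mean(record$correct[scoreable])
  structure(
    list(by_condition = rows,
         overall_percent_correct = overall,
         valid_recording = overall >= 100 * min_correct),
    class = "behavioral_summary"
  )
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf("<behavioral_summary> overall %.1f%% correct (%s)\n",
              x$overall_percent_correct,
              if (x$valid_recording) "valid" else "INVALID"))
  print(x$by_condition)
  invisible(x)
}
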