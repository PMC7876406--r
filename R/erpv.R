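#' Trial-to-trial ERP variability (ERPv)
#'
#' Computes, for one condition, the trial-by-trial standard error of the
#' amplitude at every channel and post-stimulus time point --
#' `SE(c, t) = SD_trials(c, t) / sqrt(n)` with the n-1 denominator -- and
#' averages it over all post-stimulus time points and retained channels.
#' Low ERPv reflects consistent single-trial responses; high ERPv reflects
#' a perturbed neural response to the same stimulus. With
#' `normalize = TRUE` the score is additionally divided by the RMS of the
#' condition-average post-stimulus ERP, giving a dimensionless score on a
#' roughly 0-1 scale; the raw microvolt score is always retained.
#'
#' @param epochs [eeg_epochs()] of cleaned data (broadband, not
#'   band-filtered).
#' @param condition Condition label.
#' @param normalize Also compute the normalized score.
#' @param valid_trials Optional logical/integer selector of valid trials
#'   within the condition (e.g. correct responses); defaults to all trials
#'   of the condition.
#' @return An `erpv_score` list: `condition`, `raw_erpv` (microvolts),
#'   `normalized_erpv` (or NA), `n_trials_used`, `window` (post-stimulus ms
#'   range).
#' @export
compute_erpv <- function(epochs, condition, normalize = TRUE,
                         valid_trials = NULL) {
  idx <- which(epochs$condition == condition)
  if (!is.null(valid_trials)) idx <- idx[valid_trials]
  n <- length(idx)
  if (n < 2) stop("need at least 2 valid trials for ERPv", call. = FALSE)
  post <- post_stim_idx(epochs$times)
  sub <- epochs$data[, post, idx, drop = FALSE]
  d <- dim(sub)
  flat <- matrix(sub, nrow = d[1] * d[2])       # (channel*time) x trials
  mu <- rowMeans(flat)
  ss <- rowSums((flat - mu)^2) / (n - 1)
  se <- sqrt(ss) / sqrt(n)
  raw <- mean(se)
  normalized <- NA_real_
  if (normalize) {
    rms <- sqrt(mean(mu^2))
    if (rms < 1e-12)
      stop("zero-RMS condition average: cannot normalize ERPv", call. = FALSE)
    normalized <- raw / rms
  }
  structure(
    list(condition = condition, raw_erpv = raw,
         normalized_erpv = normalized, n_trials_used = n,
         window = range(epochs$times[post])),
    class = "erpv_score"
  )
}

#' Neural-consistency complement of an ERPv score
#'
#' `1 - normalized_erpv`: larger values mean more consistent single-trial
#' responses.
#'
#' @param score An `erpv_score` (or a bare numeric normalized ERPv).
#' @return Numeric scalar.
#' @export
neural_consistency <- function(score) {
  v <- if (inherits(score, "erpv_score")) score$normalized_erpv else score
  if (is.na(v)) stop("normalized ERPv not available", call. = FALSE)
  1 - v
}

#' ERPv for every condition of a recording
#'
#' Applies [compute_erpv()] per condition, restricting to valid trials:
#' correct-response trials for response conditions, correct inhibitions for
#' NoGo, all artifact-free trials otherwise.
#'
#' @param epochs Cleaned [eeg_epochs()].
#' @param behavior Matching `behavioral_record` (aligned with the original
#'   trial order; trials dropped during cleaning are handled through
#'   `retained_trials`).
#' @param retained_trials Integer indices of the original trials that
#'   survived cleaning (default: all).
#' @param spec The [task_spec()] (identifies response/inhibition
#'   conditions).
#' @param normalize Passed to [compute_erpv()].
#' @return data.frame: `condition`, `raw_erpv`, `normalized_erpv`,
#'   `n_trials_used`.
#' @export
erpv_by_condition <- function(epochs, behavior = NULL, retained_trials = NULL,
                              spec = NULL, normalize = TRUE) {
  if (is.null(retained_trials)) retained_trials <- seq_len(dim(epochs$data)[3])
  out <- NULL
  for (cond in unique(epochs$condition)) {
    idx_in_cond <- which(epochs$condition == cond)
    valid <- rep(TRUE, length(idx_in_cond))
    if (!is.null(behavior)) {
      orig <- retained_trials[idx_in_cond]
      ok <- behavior$correct[orig]
      valid <- is.na(ok) | ok          # conditions without responses: all
    }
    if (sum(valid) < 2) next
    sc <- compute_erpv(epochs, cond, normalize = normalize,
                       valid_trials = valid)
    out <- rbind(out, data.frame(
      condition = cond, raw_erpv = sc$raw_erpv,
      normalized_erpv = sc$normalized_erpv,
      n_trials_used = sc$n_trials_used, stringsAsFactors = FALSE
    ))
  }
  out
}
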