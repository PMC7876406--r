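#' Condition-average ERP with baseline correction
#'
#' Averages the retained epochs of one condition and subtracts each
#' channel's mean over the pre-stimulus window.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param condition Condition label to average.
#' @return Numeric matrix channels x time (microvolts), with attributes
#'   `times` and `n_epochs`.
#' @export
compute_condition_erp <- function(epochs, condition) {
  idx <- which(epochs$condition == condition)
  if (!length(idx))
    stop(sprintf("no retained epochs for condition '%s'", condition),
         call. = FALSE)
  sub <- epochs$data[, , idx, drop = FALSE]
  avg <- rowMeans(sub, dims = 2)
  pre <- which(epochs$times < 0)
  if (length(pre)) {
    avg <- avg - rowMeans(avg[, pre, drop = FALSE])
  }
  attr(avg, "times") <- epochs$times
  attr(avg, "n_epochs") <- length(idx)
  avg
}
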