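#' Artifact-rejection configuration
#'
#' The cleaning rules applied to epoched EEG before analysis: absolute
#' amplitude limit (+/-100 microvolts), per-channel 7-SD epoch rule,
#' neighbor-dissimilarity threshold for bad electrodes, and a cap on the
#' number of blink components removed by ICA.
#'
#' @param amp_limit Absolute amplitude limit in microvolts.
#' @param epoch_sd_limit Per-channel SD multiple beyond which an epoch is
#'   rejected.
#' @param neighbor_sim_threshold Minimum correlation between a channel's
#'   evoked average and the average of its spatial neighbors.
#' @param bad_sample_fraction Fraction of out-of-range samples above which a
#'   channel is flagged ("extensive" sections quantified as > 5%).
#' @param max_blink_components Maximum ICA components to remove.
#' @param blink_cor_cutoff |r| between a component time course and the
#'   frontal ocular proxy above which the component is treated as a blink.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(amp_limit = 100, epoch_sd_limit = 7,
                            neighbor_sim_threshold = 0.25,
                            bad_sample_fraction = 0.05,
                            max_blink_components = 2,
                            blink_cor_cutoff = 0.6) {
  stopifnot(amp_limit > 0, epoch_sd_limit > 0,
            neighbor_sim_threshold >= -1, neighbor_sim_threshold <= 1)
  structure(
    list(amp_limit = amp_limit, epoch_sd_limit = epoch_sd_limit,
         neighbor_sim_threshold = neighbor_sim_threshold,
         bad_sample_fraction = bad_sample_fraction,
         max_blink_components = max_blink_components,
         blink_cor_cutoff = blink_cor_cutoff),
    class = "cleaning_config"
  )
}

#' Detect bad electrodes
#'
#' A channel is flagged when an extensive fraction of its samples lies
#' outside the amplitude limit, or when its evoked (across-epoch) average is
#' dissimilar to the average of its nearest spatial neighbors (correlation
#' below threshold). Correlation is judged on the across-epoch average so
#' the shared evoked signal, not channel-independent background noise,
#' drives the comparison; channels with zero-variance averages contribute no
#' correlation evidence.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param cfg A [cleaning_config()].
#' @param n_neighbors Neighbors per channel for the similarity rule.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_electrodes <- function(epochs, cfg = cleaning_config(),
                                  n_neighbors = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_ch <- dim(epochs$data)[1]
  stopifnot(n_ch >= 4)
  flat <- matrix(epochs$data, nrow = n_ch)  # channel x (time*trial)
  frac_out <- rowMeans(abs(flat) > cfg$amp_limit)
  bad_amp <- frac_out > cfg$bad_sample_fraction
  avg <- rowMeans(epochs$data, dims = 2)    # channel x time evoked average
  nb <- channel_neighbors(epochs$montage, k = n_neighbors)
  bad_cor <- logical(n_ch)
  for (ch in seq_len(n_ch)) {
    nb_mean <- colMeans(avg[nb[ch, ], , drop = FALSE])
    if (stats::sd(avg[ch, ]) < 1e-12 || stats::sd(nb_mean) < 1e-12) next
    bad_cor[ch] <- stats::cor(avg[ch, ], nb_mean) < cfg$neighbor_sim_threshold
  }
  bad <- bad_amp | bad_cor
  if (all(bad)) stop("all channels flagged as bad: unusable recording",
                     call. = FALSE)
  epochs$montage$label[bad]
}

#' Interpolate flagged channels from their neighbors
#'
#' Replaces each flagged channel, in every epoch, by the inverse-distance
#' weighted mean of its nearest good neighbors.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param bad_channels Character vector of channel labels to replace.
#' @param n_neighbors Number of good neighbors to average.
#' @return The repaired [eeg_epochs()] object.
#' @export
interpolate_channels <- function(epochs, bad_channels, n_neighbors = 4) {
  if (!length(bad_channels)) return(epochs)
  lab <- epochs$montage$label
  bad_idx <- match(bad_channels, lab)
  stopifnot(!anyNA(bad_idx))
  good_idx <- setdiff(seq_along(lab), bad_idx)
  stopifnot(length(good_idx) >= n_neighbors)
  pos <- as.matrix(epochs$montage[, c("x", "y")])
  for (ch in bad_idx) {
    d <- sqrt(colSums((t(pos[good_idx, , drop = FALSE]) - pos[ch, ])^2))
    nn <- good_idx[order(d)[seq_len(n_neighbors)]]
    w <- 1 / pmax(sort(d)[seq_len(n_neighbors)], 1e-6)
    w <- w / sum(w)
    acc <- 0
    for (j in seq_along(nn)) acc <- acc + w[j] * epochs$data[nn[j], , ]
    epochs$data[ch, , ] <- acc
  }
  epochs
}

#' Reject noisy epochs
#'
#' An epoch is removed iff any sample exceeds the absolute amplitude limit,
#' or any sample deviates more than `epoch_sd_limit` per-channel standard
#' deviations from the per-channel mean. Means and SDs are computed per
#' channel over all epochs of the same condition, and an epoch is judged on
#' its worst channel.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param cfg A [cleaning_config()].
#' @return List: `epochs` (survivors), `rejected` (integer indices into the
#'   input trials), `fraction_retained`.
#' @export
reject_noisy_epochs <- function(epochs, cfg = cleaning_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_tr <- dim(epochs$data)[3]
  stopifnot(n_tr >= 1)
  bad <- logical(n_tr)
  for (cond in unique(epochs$condition)) {
    idx <- which(epochs$condition == cond)
    sub <- epochs$data[, , idx, drop = FALSE]
    n_ch <- dim(sub)[1]
    flat <- matrix(sub, nrow = n_ch)              # channel x (time*epochs)
    mu <- rowMeans(flat)
    sdv <- sqrt(rowMeans((flat - mu)^2))
    over_amp <- if (max(abs(range(flat))) <= cfg$amp_limit) {
      FALSE    # fast path: nothing out of range anywhere
    } else {
      colSums(matrix(abs(flat) > cfg$amp_limit, ncol = length(idx))) > 0
    }
    viol <- (abs(flat - mu) > cfg$epoch_sd_limit * sdv) & (sdv > 0)
    over_sd <- colSums(matrix(viol, ncol = length(idx))) > 0
    bad[idx] <- over_amp | over_sd
  }
  if (all(bad)) stop("all epochs rejected: invalid recording", call. = FALSE)
  list(
    epochs = subset_epochs(epochs, !bad),
    rejected = which(bad),
    fraction_retained = mean(!bad)
  )
}

#' Full cleaning pass over one recording
#'
#' Runs bad-electrode detection + interpolation, blink-component removal,
#' then noisy-epoch rejection, and reports what was done. The ordering
#' (electrodes, then blink ICA, then epoch rejection) lets the ICA see all
#' epochs while ensuring rejection statistics are computed on
#' blink-corrected data.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param cfg A [cleaning_config()].
#' @param run_ica Set FALSE to skip the blink-ICA stage.
#' @return List: `epochs` (cleaned), `report` (a `cleaning_report` list with
#'   `bad_channels`, `rejected_epochs`, `removed_components`,
#'   `fraction_retained`).
#' @export
clean_epochs <- function(epochs, cfg = cleaning_config(), run_ica = TRUE) {
  bad <- detect_bad_electrodes(epochs, cfg)
  x <- interpolate_channels(epochs, bad)
  removed <- 0L
  if (run_ica && cfg$max_blink_components > 0) {
    res <- remove_blink_components(x, cfg)
    x <- res$epochs
    removed <- res$removed_components
  }
  rej <- reject_noisy_epochs(x, cfg)
  report <- structure(
    list(bad_channels = bad,
         rejected_epochs = rej$rejected,
         removed_components = removed,
         fraction_retained = rej$fraction_retained),
    class = "cleaning_report"
  )
  list(epochs = rej$epochs, report = report)
}
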