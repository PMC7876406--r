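#' Simulate epoched task EEG for one subject
#'
#' Each epoch is the sum, over the components evoked by that trial's
#' condition, of `polarity x amplitude x spatial_kernel x temporal_kernel`
#' with per-trial jittered amplitude and latency, plus additive white noise
#' and (optionally) stereotyped blink transients concentrated on frontal
#' channels. Sampling is 250 Hz by default; arrays are bit-identical for a
#' fixed seed.
#'
#' @param sequence Stimulus sequence from [generate_task_sequence()].
#' @param params A [subject_params()] object.
#' @param montage Montage data.frame.
#' @param seed Integer seed.
#' @param window Epoch window (pre_ms, post_ms) with pre_ms <= 0.
#' @param fs Sampling rate, Hz.
#' @param task Task label stored on the result.
#' @return An [eeg_epochs()] object (microvolts).
#' @export
simulate_subject_eeg <- function(sequence, params, montage, seed,
                                 window = c(-200, 1200), fs = 250,
                                 task = NULL) {
  stopifnot(nrow(montage) >= 2)
  if (nrow(unique(montage[, c("x", "y")])) < 2)
    stop("montage must have at least 2 distinct positions", call. = FALSE)
  times <- seq(window[1], window[2] - 1000 / fs, by = 1000 / fs)
  nt <- length(times)
  n_ch <- nrow(montage)
  n_tr <- nrow(sequence)
  for (cs in params$components) {
    if (cs$latency_mean <= 0 || cs$latency_mean >= window[2])
      stop(sprintf("component %s latency %.1f ms outside epoch window",
                   cs$label, cs$latency_mean), call. = FALSE)
  }
  rng <- local_rng(seed)
  # noise allocated with the array so no second full-size temporary is made
  data <- if (params$noise_sd > 0) {
    array(rng(stats::rnorm(n_ch * nt * n_tr, 0, params$noise_sd)),
          dim = c(n_ch, nt, n_tr))
  } else {
    array(0, dim = c(n_ch, nt, n_tr))
  }
  # spatial kernels are trial-invariant: precompute per component
  sp_kernels <- lapply(params$components, function(cs) {
    d2 <- (montage$x - cs$topo_center[1])^2 + (montage$y - cs$topo_center[2])^2
    exp(-d2 / (2 * cs$topo_spread^2))
  })
  for (ci in seq_along(params$components)) {
    cs <- params$components[[ci]]
    evoked <- which(sequence$condition %in% cs$conditions)
    if (!length(evoked)) next
    js <- 1
    if (!is.null(params$component_jitter_scale) &&
        !is.na(params$component_jitter_scale[cs$label]))
      js <- params$component_jitter_scale[[cs$label]]
    lat <- cs$latency_mean +
      rng(stats::rnorm(length(evoked), 0, params$trial_latency_jitter_sd * js))
    amp <- cs$polarity *
      (cs$amplitude_mean +
         rng(stats::rnorm(length(evoked), 0, params$trial_amplitude_jitter_sd * js)))
    sk <- sp_kernels[[ci]]
    # temporal kernels for all evoked trials at once: nt x n_evoked,
    # scaled per trial; one outer product adds the whole contribution
    tk <- exp(-outer(times, lat, "-")^2 / (2 * cs$kernel_sd^2))
    tk <- tk * rep(amp, each = nt)
    data[, , evoked] <- data[, , evoked, drop = FALSE] +
      array(sk %o% tk, dim = c(n_ch, nt, length(evoked)))
  }
  if (params$blink_rate > 0) {
    data <- add_blinks(data, times, montage, params$blink_rate, rng)
  }
  eeg_epochs(data, times, fs, montage, sequence$condition, task = task)
}

# Stereotyped blink model: biphasic ~300 ms transient at a virtual ocular
# site just beyond the anterior scalp edge, amplitude decaying with scalp
# distance. Counts per epoch are Poisson in the epoch duration.
add_blinks <- function(data, times, montage, rate_per_min, rng,
                       ocular_site = c(0, 1.05), peak_uv = 80,
                       spatial_scale = 0.35) {
  n_tr <- dim(data)[3]
  dur_min <- (max(times) - min(times)) / 1000 / 60
  counts <- rng(stats::rpois(n_tr, rate_per_min * dur_min))
  hit <- which(counts > 0)
  if (!length(hit)) return(data)
  d2 <- (montage$x - ocular_site[1])^2 + (montage$y - ocular_site[2])^2
  topo <- exp(-d2 / (2 * spatial_scale^2))
  for (tr in hit) {
    for (b in seq_len(counts[tr])) {
      t0 <- rng(stats::runif(1, min(times), max(times)))
      a <- peak_uv * exp(rng(stats::rnorm(1, 0, 0.2)))
      shape <- a * (exp(-((times - t0) / 70)^2) -
                      0.35 * exp(-((times - t0 - 130) / 90)^2))
      data[, , tr] <- data[, , tr] + topo %o% shape
    }
  }
  data
}

#' Blink waveform ground truth helper
#'
#' Simulates the same subject twice from one seed, with and without blinks,
#' returning both; used to evaluate blink removal against ground truth.
#' @inheritParams simulate_subject_eeg
#' @return List with elements `clean` and `blinky` ([eeg_epochs()] objects
#'   differing only by the blink transients).
#' @export
simulate_blink_pair <- function(sequence, params, montage, seed,
                                window = c(-200, 1200), fs = 250, task = NULL) {
  p0 <- params; p0$blink_rate <- 0
  clean <- simulate_subject_eeg(sequence, p0, montage, seed, window, fs, task)
  # add blinks on top of the identical clean data (separate stream)
  rng <- local_rng(derive_seed(seed, 77L))
  blinky <- clean
  blinky$data <- add_blinks(clean$data, clean$times, montage,
                            params$blink_rate, rng)
  list(clean = clean, blinky = blinky)
}

#' Simulate behavioral responses for one subject
#'
#' Response-required trials (Target, Go) are correct with probability
#' `1 - error_rate` and carry a reaction time drawn from a positive-truncated
#' normal; missed trials carry no response. Inhibition trials (NoGo) show a
#' commission error (a button press) with probability `error_rate`;
#' commissions carry an RT, correct inhibitions do not. Conditions requiring
#' no response (Frequent, Novel) are recorded with `correct = NA`.
#'
#' @param sequence Stimulus sequence.
#' @param spec The [task_spec()] the sequence came from.
#' @param params A [subject_params()] object.
#' @param seed Integer seed.
#' @return A `behavioral_record` data.frame: `trial`, `condition`,
#'   `responded`, `correct`, `rt_ms` (NA where no response).
#' @export
simulate_behavior <- function(sequence, spec, params, seed) {
  stopifnot(params$rt_sd >= 0)
  rng <- local_rng(seed)
  n <- nrow(sequence)
  responded <- logical(n)
  correct <- rep(NA, n)
  rt <- rep(NA_real_, n)
  err_of <- function(cond) {
    e <- params$error_rate[cond]
    if (is.na(e)) 0 else unname(e)
  }
  draw_rt <- function(k) {
    # positive-truncated normal via inverse CDF
    lo <- stats::pnorm(0, params$rt_mean, max(params$rt_sd, 1e-9))
    u <- rng(stats::runif(k, lo, 1))
    stats::qnorm(u, params$rt_mean, max(params$rt_sd, 1e-9))
  }
  for (cond in unique(sequence$condition)) {
    idx <- which(sequence$condition == cond)
    if (cond %in% spec$response_conditions) {
      ok <- rng(stats::runif(length(idx))) >= err_of(cond)
      correct[idx] <- ok
      responded[idx] <- ok
      if (any(ok)) rt[idx[ok]] <- draw_rt(sum(ok))
    } else if (cond %in% spec$inhibition_conditions) {
      commission <- rng(stats::runif(length(idx))) < err_of(cond)
      correct[idx] <- !commission
      responded[idx] <- commission
      if (any(commission)) rt[idx[commission]] <- draw_rt(sum(commission))
    }
  }
  structure(
    data.frame(trial = sequence$trial, condition = sequence$condition,
               responded = responded, correct = correct, rt_ms = rt,
               stringsAsFactors = FALSE),
    class = c("behavioral_record", "data.frame")
  )
}
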