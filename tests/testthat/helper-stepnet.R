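# Shared fixtures for the test suite. Everything is generated in code; the
# expensive simulated reference group is built once per session and cached.

.test_cache <- new.env(parent = emptyenv())

# 120-member simulated normative reference (Novel condition, delta band),
# shared by the percentile-calibration and effect-recovery suites.
cached_reference <- function() {
  if (is.null(.test_cache$ref)) {
    .test_cache$ref <- build_simulated_reference(n_members = 120, seed = 42)
  }
  .test_cache$ref
}

# small epoched set: shared stimulus-locked signal + white noise
make_test_epochs <- function(n_ch = 16, n_t = 150, n_tr = 30, noise_sd = 1,
                             signal_gain = 5, fs = 250, seed = 1,
                             condition = rep("A", n_tr)) {
  mon <- make_montage(n_ch)
  times <- seq(-200, by = 1000 / fs, length.out = n_t)
  base <- signal_gain * sin(2 * pi * 5 * times / 1000)
  set.seed(seed)
  data <- array(stats::rnorm(n_ch * n_t * n_tr, 0, noise_sd),
                c(n_ch, n_t, n_tr))
  data <- data + rep(rep(base, each = n_ch), n_tr)
  eeg_epochs(data, times, fs, mon, condition)
}

# single-component noiseless subject: P3a-like bump, deterministic
make_noiseless_subject <- function(latency = 300, amplitude = 5,
                                   n_trials = 10, montage = make_montage(64),
                                   kernel_sd = 60, seed = 3) {
  cs <- component_spec("P3a", 1, c(0, 0.2), 0.5, latency, 0, amplitude, 0,
                       kernel_sd = kernel_sd, band = "delta",
                       conditions = "Novel")
  par <- subject_params("healthy", list(cs),
                        trial_latency_jitter_sd = 0,
                        trial_amplitude_jitter_sd = 0,
                        noise_sd = 0, blink_rate = 0)
  spec <- task_spec("AOB", n_trials = n_trials,
                    condition_probs = c(Frequent = 0, Target = 0, Novel = 1))
  sq <- generate_task_sequence(spec, seed)
  simulate_subject_eeg(sq, par, montage, seed + 1)
}

# smooth random 3-d field on a fully unmasked grid, as an erp_grid
make_random_grid <- function(d = c(16, 16, 50), seed = 1, scale = 5,
                             pre_samples = 10, fs = 250) {
  set.seed(seed)
  sm <- array(stats::rnorm(prod(d)), d)
  for (k in 1:2) {
    sm <- (sm +
             sm[c(1, seq_len(d[1] - 1)), , ] + sm[c(2:d[1], d[1]), , ] +
             sm[, c(1, seq_len(d[2] - 1)), ] + sm[, c(2:d[2], d[2]), ] +
             sm[, , c(1, seq_len(d[3] - 1))] + sm[, , c(2:d[3], d[3])]) / 7
  }
  times <- seq(-pre_samples * 1000 / fs, by = 1000 / fs, length.out = d[3])
  structure(
    list(values = sm * scale, xs = seq(-1, 1, length.out = d[1]),
         ys = seq(-1, 1, length.out = d[2]), times = times,
         band = NULL, condition = NULL),
    class = "erp_grid"
  )
}

# independent brute-force STEP oracle: exhaustive scan of every grid point
# against its full 3x3x3 neighborhood (loop-based, no shared code with
# extract_steps)
brute_force_steps <- function(grid, min_abs) {
  vals <- grid$values
  d <- dim(vals)
  out <- NULL
  for (ix in 1:d[1]) for (iy in 1:d[2]) for (it in 2:(d[3] - 1)) {
    if (grid$times[it] < 0) next
    v <- vals[ix, iy, it]
    if (is.na(v) || abs(v) < min_abs) next
    nb <- c()
    for (jx in max(1, ix - 1):min(d[1], ix + 1))
      for (jy in max(1, iy - 1):min(d[2], iy + 1))
        for (jt in (it - 1):(it + 1)) {
          if (jx == ix && jy == iy && jt == it) next
          nb <- c(nb, vals[jx, jy, jt])
        }
    nb <- nb[!is.na(nb)]
    if ((v > 0 && all(v > nb)) || (v < 0 && all(v < nb)))
      out <- rbind(out, data.frame(ix = ix, iy = iy, it = it, amplitude = v))
  }
  out
}

# synthetic STEP table builder for clustering/matching tests
make_step_table <- function(time_ms, x, y, amplitude,
                            band = "delta", condition = "Novel") {
  n <- length(time_ms)
  data.frame(
    amplitude = amplitude, time_ms = time_ms, x = x, y = y,
    ix = rep(NA_integer_, n), iy = rep(NA_integer_, n),
    it = rep(NA_integer_, n),
    polarity = sign(amplitude), n_surround = rep(NA_integer_, n),
    band = rep(band, n), condition = rep(condition, n),
    stringsAsFactors = FALSE
  )
}

# independent sums-of-squares oracle for the split-plot between-group F
split_plot_F_oracle <- function(tab) {
  wide <- reshape(tab, idvar = c("subject", "group"), timevar = "visit",
                  direction = "wide")
  y <- as.matrix(wide[, grep("^score", names(wide))])
  k <- ncol(y)
  subj_mean <- rowMeans(y)
  grand <- mean(y)
  grp <- split(seq_len(nrow(wide)), wide$group)
  ss_group <- k * sum(vapply(grp, function(ii)
    length(ii) * (mean(subj_mean[ii]) - grand)^2, 0))
  ss_subj_within <- k * sum(vapply(grp, function(ii)
    sum((subj_mean[ii] - mean(subj_mean[ii]))^2), 0))
  df1 <- length(grp) - 1
  df2 <- nrow(wide) - length(grp)
  (ss_group / df1) / (ss_subj_within / df2)
}

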