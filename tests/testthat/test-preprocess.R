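test_that("amplitude-saturated channels are flagged as bad electrodes", {
  ep <- make_test_epochs(n_ch = 16, seed = 1)
  ep$data[3, , ] <- 150
  expect_identical(detect_bad_electrodes(ep), "E03")
})

test_that("identical signals on every channel flag nothing", {
  ep <- make_test_epochs(n_ch = 16, noise_sd = 0, seed = 2)
  expect_length(detect_bad_electrodes(ep), 0)
})

test_that("a channel carrying independent noise among correlated channels is flagged", {
  ep <- make_test_epochs(n_ch = 16, noise_sd = 1, signal_gain = 5, seed = 3)
  set.seed(4)
  ep$data[5, , ] <- stats::rnorm(prod(dim(ep$data)[2:3]), 0, 5)
  expect_identical(detect_bad_electrodes(ep), "E05")
})

test_that("a fully saturated recording is a hard failure", {
  ep <- make_test_epochs(n_ch = 8, seed = 5)
  ep$data[] <- 200
  expect_error(detect_bad_electrodes(ep), "unusable")
})

test_that("flagged channels are interpolated from neighbors", {
  ep <- make_test_epochs(n_ch = 16, noise_sd = 0.5, signal_gain = 5, seed = 6)
  truth <- ep$data[3, , ]
  ep$data[3, , ] <- 500
  fixed <- interpolate_channels(ep, "E03")
  # interpolation recovers the shared signal to within the noise level
  expect_lt(mean((fixed$data[3, , ] - truth)^2), 1)
  expect_identical(fixed$data[-3, , ], ep$data[-3, , ])
})

test_that("epochs beyond the amplitude limit are rejected", {
  ep <- make_test_epochs(n_ch = 8, n_tr = 20, noise_sd = 1, seed = 7)
  ep$data[1, 50, 7] <- 120
  res <- reject_noisy_epochs(ep)
  expect_equal(res$rejected, 7)
  expect_equal(dim(res$epochs$data)[3], 19)
  expect_equal(res$fraction_retained, 19 / 20)
})

test_that("all-zero epochs are all retained and rejection is idempotent", {
  mon <- make_montage(8)
  data <- array(0, c(8, 50, 10))
  ep <- eeg_epochs(data, seq(-196, by = 4, length.out = 50), 250, mon,
                   rep("A", 10))
  res <- reject_noisy_epochs(ep)
  expect_length(res$rejected, 0)
  # idempotence on a realistic set with planted outliers
  ep2 <- make_test_epochs(n_ch = 8, n_tr = 30, noise_sd = 1, seed = 8)
  ep2$data[2, 10, c(3, 11)] <- c(150, -130)
  pass1 <- reject_noisy_epochs(ep2)
  pass2 <- reject_noisy_epochs(pass1$epochs)
  expect_length(pass2$rejected, 0)
})

test_that("exactly the planted SD-rule violators are removed", {
  mon <- make_montage(8)
  set.seed(9)
  n_tr <- 40
  data <- array(stats::rnorm(8 * 60 * n_tr), c(8, 60, n_tr))
  planted <- c(5, 17, 33)
  # large excursions, still inside the +/-100 limit, far beyond 7 SD
  for (j in planted) data[3, 20, j] <- 40
  ep <- eeg_epochs(data, seq(-196, by = 4, length.out = 60), 250, mon,
                   rep("A", n_tr))
  res <- reject_noisy_epochs(ep)
  expect_equal(res$rejected, planted)
})

test_that("rejection is invariant to epoch order", {
  ep <- make_test_epochs(n_ch = 8, n_tr = 25, noise_sd = 1, seed = 10)
  ep$data[4, 30, c(2, 14)] <- 130
  res <- reject_noisy_epochs(ep)
  perm <- sample(25)
  ep_p <- subset_epochs(ep, perm)
  res_p <- reject_noisy_epochs(ep_p)
  expect_setequal(perm[res_p$rejected], res$rejected)
})

test_that("rejecting every epoch is an error", {
  mon <- make_montage(8)
  data <- array(200, c(8, 20, 5))
  ep <- eeg_epochs(data, seq(-76, by = 4, length.out = 20), 250, mon,
                   rep("A", 5))
  expect_error(reject_noisy_epochs(ep), "all epochs rejected")
})

test_that("blink ICA reduces the distance to blink-free ground truth", {
  sq <- generate_task_sequence(
    task_spec("AOB", n_trials = 60,
              condition_probs = c(Frequent = 1, Target = 0, Novel = 0)), 1)
  par <- draw_subject_params("healthy", "AOB", seed = 2, blink_rate = 8)
  mon <- make_montage(64)
  pair <- simulate_blink_pair(sq, par, mon, 3)
  res <- remove_blink_components(pair$blinky, cleaning_config())
  expect_gte(res$removed_components, 1)
  mse_before <- mean((pair$blinky$data - pair$clean$data)^2)
  mse_after <- mean((res$epochs$data - pair$clean$data)^2)
  expect_lt(mse_after, mse_before)
})

test_that("without blinks the ICA stage leaves the data essentially unchanged", {
  sq <- generate_task_sequence(
    task_spec("AOB", n_trials = 40,
              condition_probs = c(Frequent = 1, Target = 0, Novel = 0)), 1)
  par <- draw_subject_params("healthy", "AOB", seed = 4, blink_rate = 0)
  ee <- simulate_subject_eeg(sq, par, make_montage(32), 5)
  res <- remove_blink_components(ee, cleaning_config())
  for (ch in seq_len(32)) {
    expect_gt(stats::cor(as.numeric(res$epochs$data[ch, , ]),
                         as.numeric(ee$data[ch, , ])), 0.99)
  }
})

test_that("a zero blink-component budget passes data through untouched", {
  ep <- make_test_epochs(n_ch = 16, n_tr = 30, seed = 11)
  res <- remove_blink_components(ep, cleaning_config(max_blink_components = 0))
  expect_identical(res$epochs$data, ep$data)
  expect_equal(res$removed_components, 0L)
})

test_that("the full cleaning pass preserves channel count and reports every stage", {
  ep <- make_test_epochs(n_ch = 16, n_tr = 30, noise_sd = 1, seed = 12)
  ep$data[2, 5, 4] <- 150
  out <- clean_epochs(ep, run_ica = FALSE)
  expect_equal(dim(out$epochs$data)[1], 16)
  expect_true(4 %in% out$report$rejected_epochs)
  expect_equal(out$report$fraction_retained,
               dim(out$epochs$data)[3] / 30)
})
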