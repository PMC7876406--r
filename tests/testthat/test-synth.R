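test_that("stimulus sequences have exact per-condition counts and conserve the total", {
  sq <- generate_task_sequence(task_spec("AOB"), seed = 1)
  expect_equal(nrow(sq), 600)
  tb <- table(sq$condition)
  expect_equal(unname(tb[c("Frequent", "Target", "Novel")]),
               as.table(c(480L, 60L, 60L)), ignore_attr = TRUE)
  gng <- generate_task_sequence(task_spec("GNG"), seed = 2)
  expect_equal(sum(table(gng$condition)), 300)
  # count conservation under awkward probabilities
  sp <- task_spec("AOB", n_trials = 100,
                  condition_probs = c(Frequent = 1 / 3, Target = 1 / 3,
                                      Novel = 1 / 3))
  expect_equal(sum(table(generate_task_sequence(sp, 3)$condition)), 100)
})

test_that("sequences are deterministic for a fixed seed and ISIs respect the range", {
  s1 <- generate_task_sequence(task_spec("AOB"), seed = 7)
  s2 <- generate_task_sequence(task_spec("AOB"), seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, generate_task_sequence(task_spec("AOB"), seed = 8)))
  gng <- generate_task_sequence(task_spec("GNG"), seed = 4)
  isi <- diff(c(0, gng$onset_ms))
  expect_true(all(isi >= 1000 & isi <= 2000))
  # AOB is presented at a fixed 1.5 s rate
  aob <- generate_task_sequence(task_spec("AOB"), seed = 4)
  expect_true(all(diff(aob$onset_ms) == 1500))
})

test_that("invalid condition probabilities are a configuration error", {
  expect_error(task_spec("AOB", condition_probs = c(Frequent = 0.9, Target = 0.2,
                                                    Novel = 0.1)),
               "sum to 1")
})

test_that("noiseless single-component simulation reproduces the planted peak exactly", {
  mon <- make_montage(64)
  ee <- make_noiseless_subject(latency = 300, amplitude = 5, montage = mon)
  erp <- compute_condition_erp(ee, "Novel")
  peak_ch <- which.max(apply(erp, 1, max))
  # the planted topography is centred at (0, 0.2)
  expect_lt(sqrt(mon$x[peak_ch]^2 + (mon$y[peak_ch] - 0.2)^2), 1e-6)
  expect_equal(max(erp[peak_ch, ]), 5, tolerance = 1e-4)
  expect_equal(ee$times[which.max(erp[peak_ch, ])], 300)
})

test_that("component latency outside the epoch window is a configuration error", {
  cs <- component_spec("P3a", 1, c(0, 0.2), 0.5, 1500, 0, 5, 0,
                       conditions = "Novel")
  par <- subject_params("healthy", list(cs), 0, 0, 0, 0)
  sq <- generate_task_sequence(
    task_spec("AOB", n_trials = 5,
              condition_probs = c(Frequent = 0, Target = 0, Novel = 1)), 1)
  expect_error(simulate_subject_eeg(sq, par, make_montage(8), 1),
               "outside epoch window")
})

test_that("latency jitter smears the averaged ERP peak", {
  mon <- make_montage(8)
  spec <- task_spec("AOB", n_trials = 500,
                    condition_probs = c(Frequent = 0, Target = 0, Novel = 1))
  sq <- generate_task_sequence(spec, 1)
  cs <- component_spec("P3a", 1, c(0, 0.2), 0.5, 300, 0, 5, 0,
                       kernel_sd = 40, band = "delta", conditions = "Novel")
  peak_for <- function(jit) {
    par <- subject_params("healthy", list(cs),
                          trial_latency_jitter_sd = jit,
                          trial_amplitude_jitter_sd = 0, noise_sd = 0,
                          blink_rate = 0)
    ee <- simulate_subject_eeg(sq, par, mon, 11)
    max(compute_condition_erp(ee, "Novel"))
  }
  expect_lt(peak_for(40), peak_for(0))
})

test_that("simulated EEG is bit-identical across runs with one seed", {
  sq <- generate_task_sequence(
    task_spec("AOB", n_trials = 10,
              condition_probs = c(Frequent = 0.8, Target = 0.1, Novel = 0.1)), 5)
  par <- draw_subject_params("healthy", "AOB", seed = 5)
  a <- simulate_subject_eeg(sq, par, make_montage(8), 99)
  b <- simulate_subject_eeg(sq, par, make_montage(8), 99)
  expect_identical(a$data, b$data)
})

test_that("trial-to-trial variance grows with noise and amplitude jitter", {
  mon <- make_montage(8)
  spec <- task_spec("AOB", n_trials = 60,
                    condition_probs = c(Frequent = 0, Target = 0, Novel = 1))
  sq <- generate_task_sequence(spec, 2)
  cs <- component_spec("P3a", 1, c(0, 0.2), 0.5, 300, 0, 5, 0,
                       conditions = "Novel")
  trial_var <- function(noise_sd, amp_jit) {
    par <- subject_params("healthy", list(cs),
                          trial_latency_jitter_sd = 0,
                          trial_amplitude_jitter_sd = amp_jit,
                          noise_sd = noise_sd, blink_rate = 0)
    ee <- simulate_subject_eeg(sq, par, mon, 21)
    flat <- matrix(ee$data, nrow = prod(dim(ee$data)[1:2]))
    mean(apply(flat, 1, stats::var))
  }
  v_noise <- vapply(c(2, 5, 10), trial_var, 0, amp_jit = 0)
  expect_true(all(diff(v_noise) > 0))
  v_jit <- vapply(c(0, 2, 4), function(j) trial_var(1, j), 0)
  expect_true(all(diff(v_jit) > 0))
})

test_that("behavioral simulation honors error rates, truncation and determinism", {
  spec <- task_spec("AOB")
  sq <- generate_task_sequence(spec, 1)
  par <- subject_params("healthy", list(), rt_mean = 450, rt_sd = 90,
                        error_rate = c(Target = 0))
  beh <- simulate_behavior(sq, spec, par, 2)
  tgt <- beh[beh$condition == "Target", ]
  expect_true(all(tgt$correct))
  expect_true(all(tgt$rt_ms > 0))
  expect_true(all(is.na(beh$correct[beh$condition %in% c("Frequent", "Novel")])))
  expect_identical(beh, simulate_behavior(sq, spec, par, 2))
  # responses carry RTs iff responded
  expect_true(all(is.na(beh$rt_ms) == !beh$responded))
})

test_that("patient reaction times reproduce the configured distribution", {
  spec <- task_spec("AOB")
  sq <- generate_task_sequence(spec, 3)
  par <- subject_params("patient", list(), rt_mean = 570.68, rt_sd = 119.31,
                        error_rate = c(Target = 0))
  # pool several sequences so n is large enough for a tight check
  rts <- unlist(lapply(1:10, function(s)
    simulate_behavior(sq, spec, par, s)$rt_ms))
  rts <- rts[!is.na(rts)]
  se <- 119.31 / sqrt(length(rts))
  expect_lt(abs(mean(rts) - 570.68), 3 * se + 1)  # +1 ms truncation allowance
})

test_that("NoGo commission errors carry reaction times, correct inhibitions do not", {
  spec <- task_spec("GNG")
  sq <- generate_task_sequence(spec, 9)
  par <- subject_params("patient", list(), rt_mean = 500, rt_sd = 100,
                        error_rate = c(Go = 0.1, NoGo = 0.5))
  beh <- simulate_behavior(sq, spec, par, 4)
  ng <- beh[beh$condition == "NoGo", ]
  expect_true(any(!ng$correct))
  expect_true(all(!is.na(ng$rt_ms[!ng$correct])))
  expect_true(all(is.na(ng$rt_ms[ng$correct])))
})

test_that("cohorts have the configured group structure and reproduce exactly", {
  cfg <- cohort_config(
    n_healthy = 30, n_patient = 9, visits = 2, seed = 3,
    tasks = list(task_spec("AOB", n_trials = 10,
                           condition_probs = c(Frequent = 0.8, Target = 0.1,
                                               Novel = 0.1))))
  co <- generate_cohort(cfg, include_eeg = FALSE)
  expect_equal(table(co$subjects$group),
               as.table(c(healthy = 30L, patient = 9L)), ignore_attr = TRUE)
  expect_length(co$cells, 39)
  expect_length(co$cells[[1]], 2)
  co2 <- generate_cohort(cfg, include_eeg = FALSE)
  expect_identical(co$cells[["S001"]][[1]]$AOB$behavior,
                   co2$cells[["S001"]][[1]]$AOB$behavior)
})

test_that("with a null group effect the mixed ANOVA rejects at about the nominal rate", {
  # behavioral scores from exchangeable groups: type-I error over replicates
  spec <- task_spec("AOB", n_trials = 40,
                    condition_probs = c(Frequent = 0.5, Target = 0.5, Novel = 0))
  cfg0 <- cohort_config(n_healthy = 30, n_patient = 9, visits = 2,
                        group_effect = null_group_effect(), seed = 1,
                        tasks = list(spec))
  n_reps <- 200
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg0$seed <- derive_seed(1, 500L, r)
    co <- generate_cohort(cfg0, include_eeg = FALSE)
    rows <- NULL
    for (id in co$subjects$id) {
      for (v in 1:2) {
        beh <- co$cells[[id]][[v]]$AOB$behavior
        rows <- rbind(rows, data.frame(
          subject = id, visit = v,
          group = co$subjects$group[co$subjects$id == id],
          score = mean(beh$rt_ms, na.rm = TRUE)))
      }
    }
    rej[r] <- mixed_anova(rows)$p < 0.05
  }
  expect_gte(mean(rej), 0.015)
  expect_lte(mean(rej), 0.10)
})

test_that("cohort demographics are metadata in the adolescent range", {
  cfg <- cohort_config(n_healthy = 5, n_patient = 3, visits = 1,
                       tasks = list(task_spec("AOB", n_trials = 5,
                                              condition_probs = c(Frequent = 1, Target = 0, Novel = 0))),
                       seed = 2)
  co <- generate_cohort(cfg, include_eeg = FALSE)
  dem <- cohort_demographics(co, seed = 1)
  expect_equal(nrow(dem), 8)
  expect_true(all(dem$age_years >= 14 & dem$age_years <= 18))
  expect_true(all(dem$age_months >= 0 & dem$age_months <= 11))
})
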