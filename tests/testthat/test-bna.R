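test_that("averaging identical epochs returns the single epoch after baseline", {
  mon <- make_montage(8)
  times <- seq(-200, 596, by = 4)
  one <- matrix(stats::rnorm(8 * length(times)), 8)
  data <- array(rep(one, 5), c(8, length(times), 5))
  ep <- eeg_epochs(data, times, 250, mon, rep("Novel", 5))
  avg <- compute_condition_erp(ep, "Novel")
  base <- rowMeans(one[, times < 0])
  expect_equal(unclass(avg), one - base, ignore_attr = TRUE)
})

test_that("baseline correction zeroes the pre-stimulus mean under constant offsets", {
  mon <- make_montage(8)
  times <- seq(-200, 596, by = 4)
  data <- array(7.3, c(8, length(times), 4))
  ep <- eeg_epochs(data, times, 250, mon, rep("A", 4))
  avg <- compute_condition_erp(ep, "A")
  expect_equal(max(abs(rowMeans(avg[, times < 0]))), 0)
  expect_error(compute_condition_erp(ep, "B"), "no retained epochs")
})

test_that("residual noise in the average shrinks like one over root n", {
  mon <- make_montage(8)
  times <- seq(-200, 596, by = 4)
  signal <- 5 * exp(-(times - 300)^2 / (2 * 60^2))
  resid_sd <- vapply(c(10, 40, 160), function(n) {
    set.seed(n)
    data <- array(stats::rnorm(8 * length(times) * n, 0, 4),
                  c(8, length(times), n))
    data <- data + rep(rep(signal, each = 8), n)
    ep <- eeg_epochs(data, times, 250, mon, rep("A", n))
    avg <- compute_condition_erp(ep, "A")
    stats::sd(avg[1, times >= 0] - (signal[times >= 0] - mean(signal[times < 0])))
  }, 0)
  expect_equal(resid_sd[1] / resid_sd[2], 2, tolerance = 0.35)
  expect_equal(resid_sd[2] / resid_sd[3], 2, tolerance = 0.35)
})

test_that("grid interpolation is exact at electrodes and constant for constant input", {
  # montage chosen on grid nodes of a 21 x 21 grid (step 0.1)
  mon <- data.frame(label = sprintf("E%02d", 1:8),
                    x = c(0, 0.5, 0, -0.5, 0, 0.3, -0.3, 0.2),
                    y = c(0, 0, 0.5, 0, -0.5, 0.3, -0.3, -0.6))
  erp <- matrix(c(1, 4, 2, -3, 0.5, 2.5, -1, 3), 8, 1)
  g <- interpolate_grid(erp, mon, times = 0, resolution = c(21, 21))
  ix <- match(0.5, g$xs); iy <- match(0, g$ys)
  expect_equal(g$values[ix, iy, 1], 4, tolerance = 1e-8)
  ix0 <- match(0, g$xs); iy0 <- match(0, g$ys)
  expect_equal(g$values[ix0, iy0, 1], 1, tolerance = 1e-8)
  # constant input: constant on the head mask
  gc <- interpolate_grid(matrix(2, 8, 1), mon, times = 0, resolution = c(21, 21))
  expect_equal(range(gc$values, na.rm = TRUE), c(2, 2), tolerance = 1e-8)
  # nodes outside the head disc are masked
  expect_true(is.na(gc$values[1, 1, 1]))
})

test_that("a single-channel hot spot lands within one grid cell of the electrode", {
  mon <- make_montage(16)
  erp <- matrix(0, 16, 1)
  hot <- 7
  erp[hot, 1] <- 10
  g <- interpolate_grid(erp, mon, times = 0, resolution = c(32, 32))
  idx <- which(g$values[, , 1] == max(g$values, na.rm = TRUE), arr.ind = TRUE)
  cell <- 2 / 31
  expect_lt(abs(g$xs[idx[1]] - mon$x[hot]), cell * 1.5)
  expect_lt(abs(g$ys[idx[2]] - mon$y[hot]), cell * 1.5)
})

test_that("degenerate (collinear) montages are rejected", {
  mon <- data.frame(label = sprintf("E%02d", 1:4),
                    x = c(0, 0.2, 0.4, 0.6), y = c(0, 0.2, 0.4, 0.6))
  expect_error(make_grid_mapper(mon), "degenerate")
})

test_that("a single smooth bump yields exactly one STEP at its maximum", {
  ee <- make_noiseless_subject(latency = 300, amplitude = 5)
  erp <- compute_condition_erp(ee, "Novel")
  g <- interpolate_grid(erp, ee$montage, ee$times, band = "delta",
                        condition = "Novel")
  st <- extract_steps(g, 1)
  expect_equal(nrow(st), 1)
  expect_equal(st$polarity, 1)
  expect_equal(st$time_ms, 300, tolerance = 4)
  expect_lt(sqrt(st$x^2 + (st$y - 0.2)^2), 0.1)
})

test_that("two well-separated opposite bumps yield two STEPs matching brute force", {
  grid <- make_random_grid(d = c(16, 16, 50), seed = 100, scale = 0)
  ts <- grid$times
  bump1 <- 8 * exp(-(ts - 80)^2 / (2 * 30^2))
  bump2 <- -6 * exp(-(ts - 140)^2 / (2 * 30^2))
  for (ix in 1:16) for (iy in 1:16) {
    w1 <- exp(-((ix - 5)^2 + (iy - 5)^2) / 8)
    w2 <- exp(-((ix - 12)^2 + (iy - 12)^2) / 8)
    grid$values[ix, iy, ] <- w1 * bump1 + w2 * bump2
  }
  st <- extract_steps(grid, 1)
  expect_equal(nrow(st), 2)
  expect_setequal(st$polarity, c(1, -1))
  bf <- brute_force_steps(grid, 1)
  expect_equal(nrow(st), nrow(bf))
  expect_setequal(paste(st$ix, st$iy, st$it), paste(bf$ix, bf$iy, bf$it))
})

test_that("every surround point keeps at least half the peak amplitude and touches the peak", {
  ee <- make_noiseless_subject(latency = 300, amplitude = 10)
  erp <- compute_condition_erp(ee, "Novel")
  g <- interpolate_grid(erp, ee$montage, ee$times, band = "delta",
                        condition = "Novel")
  st <- extract_steps(g, 1, compute_surround = TRUE)
  surr <- st$surround[[1]]
  vals <- g$values[surr]
  expect_true(all(vals >= 0.5 * st$amplitude[1]))
  expect_true(all(sign(vals) == st$polarity[1]))
  # the peak itself belongs to its surround
  expect_true(any(surr[, 1] == st$ix[1] & surr[, 2] == st$iy[1] &
                    surr[, 3] == st$it[1]))
  expect_equal(st$n_surround[1], nrow(surr))
})

test_that("STEP extraction matches the exhaustive scan on random smooth fields", {
  for (s in 1:20) {
    grid <- make_random_grid(seed = 200 + s)
    st <- extract_steps(grid, 1, compute_surround = FALSE)
    bf <- brute_force_steps(grid, 1)
    n_bf <- if (is.null(bf)) 0L else nrow(bf)
    expect_equal(nrow(st), n_bf)
    if (n_bf > 0) {
      expect_setequal(paste(st$ix, st$iy, st$it), paste(bf$ix, bf$iy, bf$it))
    }
    # sorted by decreasing magnitude
    expect_true(!is.unsorted(rev(abs(st$amplitude))))
  }
})

test_that("clustering keeps peaks shared by enough subjects and drops the rest", {
  # ten subjects with an identical STEP: one cluster at full prevalence
  steps <- lapply(1:10, function(i) make_step_table(300, 0.1, 0.2, 6))
  names(steps) <- sprintf("S%02d", 1:10)
  ms <- cluster_steps(steps)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$prevalence, 1)
  expect_equal(ms$centroid_time, 300)
  # present in only 6 of 10 subjects: below the 70% prevalence floor
  steps2 <- steps
  for (i in 7:10) steps2[[i]] <- make_step_table(numeric(0), numeric(0),
                                                 numeric(0), numeric(0))
  expect_equal(nrow(cluster_steps(steps2)), 0)
})

test_that("two planted STEP populations are recovered with accurate centroids", {
  set.seed(31)
  n <- 24
  steps <- lapply(1:n, function(i) {
    make_step_table(
      time_ms = c(100 + stats::rnorm(1, 0, 20), 300 + stats::rnorm(1, 0, 20)),
      x = stats::rnorm(2, 0, 0.03), y = stats::rnorm(2, 0.2, 0.03),
      amplitude = c(5, 6))
  })
  names(steps) <- sprintf("S%02d", 1:n)
  ms <- cluster_steps(steps)
  expect_equal(nrow(ms), 2)
  expect_lt(abs(ms$centroid_time[1] - 100), 10)
  expect_lt(abs(ms$centroid_time[2] - 300), 10)
  expect_true(all(ms$prevalence == 1))
})

test_that("canonical component labels attach by latency window and polarity", {
  ms <- cluster_steps(stats::setNames(
    lapply(1:4, function(i) make_step_table(c(100, 300), c(0, 0), c(0.3, 0.2),
                                            c(-4, 6))), sprintf("S%d", 1:4)))
  ms <- label_main_steps(ms)
  expect_equal(ms$component[order(ms$centroid_time)], c("N100", "P3a"))
})

test_that("matching follows the window rule and prefers the nearer candidate", {
  ms <- cluster_steps(stats::setNames(
    lapply(1:4, function(i) make_step_table(300, 0, 0.2, 6)),
    sprintf("S%d", 1:4)))
  # exact hit: distance zero
  hit <- match_steps(make_step_table(300, 0, 0.2, 5), ms)
  expect_true(hit$matched)
  expect_equal(hit$distance, 0)
  # 300 ms away with a 100 ms window: unmatched
  far <- match_steps(make_step_table(600, 0, 0.2, 5), ms,
                     window_dt_ms = 100, window_ds = 0.25)
  expect_false(far$matched)
  # polarity must agree
  wrong_pol <- match_steps(make_step_table(300, 0, 0.2, -5), ms)
  expect_false(wrong_pol$matched)
  # two candidates at 20 and 60 ms, same spatial offset: nearer wins
  two <- make_step_table(c(320, 360), c(0, 0), c(0.2, 0.2), c(5, 5))
  got <- match_steps(two, ms)
  expect_true(got$matched)
  expect_equal(got$time_ms, 320)
})

test_that("percentile scores follow the mid-rank formula and are monotone", {
  expect_equal(percentile_score(10, c(1, 2, 3)), 100)
  expect_equal(percentile_score(0, c(1, 2, 3)), 0)
  expect_equal(percentile_score(2, c(1, 2, 3, 4)), 37.5)
  v <- seq(-3, 3, by = 0.5)
  ref <- stats::rnorm(50)
  expect_true(!is.unsorted(percentile_score(v, ref)))
  expect_error(percentile_score(1, numeric(0)), "empty")
})

test_that("reference groups store sorted member values and record membership", {
  steps <- lapply(1:12, function(i) make_step_table(300 + i, 0, 0.2, 6 + i / 10))
  names(steps) <- sprintf("S%02d", 1:12)
  ms <- cluster_steps(steps)
  ref <- build_reference_group(steps, ms)
  expect_equal(ref$n_members, 12)
  lab <- ref$main_steps$label[1]
  expect_equal(ref$values[[lab]]$latency, 301:312)
  expect_true(!is.unsorted(ref$values[[lab]]$amplitude))
  # identical members give constant value lists
  same <- lapply(1:6, function(i) make_step_table(300, 0, 0.2, 6))
  names(same) <- sprintf("T%d", 1:6)
  ms2 <- cluster_steps(same)
  ref2 <- build_reference_group(same, ms2)
  expect_equal(length(unique(ref2$values[[1]]$latency)), 1)
})

test_that("templates matched by under half the members are dropped with a warning", {
  steps <- lapply(1:10, function(i) {
    if (i <= 4) make_step_table(c(100, 500), c(0, 0.5), c(0.3, -0.5), c(-4, 3))
    else make_step_table(100, 0, 0.3, -4)
  })
  names(steps) <- sprintf("S%02d", 1:10)
  ms <- cluster_steps(steps, prevalence_min = 0.3)
  expect_equal(nrow(ms), 2)
  expect_warning(ref <- build_reference_group(steps, ms), "dropping")
  expect_equal(nrow(ref$main_steps), 1)
})

test_that("a latency-shifted subject scores above the 90th percentile", {
  # noiseless members whose P3a latencies tile 264..340 ms on the sample
  # grid (4 ms steps), so measured latencies are distinct and rankable
  mon <- make_montage(32)
  members <- lapply(1:20, function(i)
    make_noiseless_subject(latency = 260 + 4 * i, amplitude = 6,
                           montage = mon, seed = 40 + i))
  registry <- data.frame(condition = "Novel", band = "delta")
  member_steps <- lapply(members, function(ee)
    subject_steps(ee, registry, resolution = c(24, 24))[[1]])
  names(member_steps) <- sprintf("M%02d", 1:20)
  ms <- label_main_steps(cluster_steps(member_steps))
  ref <- build_reference_group(member_steps, ms)
  ref$main_steps <- label_main_steps(ref$main_steps)
  shifted <- make_noiseless_subject(latency = 300 + 60, amplitude = 6,
                                    montage = mon, seed = 99)
  sc <- score_subject(shifted, ref, resolution = c(24, 24))
  lat <- sc[sc$attribute == "latency", ]
  expect_true(all(lat$matched))
  expect_gt(lat$percentile, 90)
  # the member at the median latency scores near the middle
  med <- score_subject(members[[10]], ref, resolution = c(24, 24))
  med_lat <- med[med$attribute == "latency", ]
  expect_gte(med_lat$percentile, 40)
  expect_lte(med_lat$percentile, 60)
})

test_that("scoring against an empty template registry yields an empty score list", {
  ref <- structure(list(main_steps = cluster_steps(list(
    A = make_step_table(numeric(0), numeric(0), numeric(0), numeric(0)),
    B = make_step_table(numeric(0), numeric(0), numeric(0), numeric(0)))),
    values = list(), match_rate = numeric(0), n_members = 0),
    class = "reference_group")
  ee <- make_noiseless_subject()
  expect_equal(nrow(score_subject(ee, ref)), 0)
})
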