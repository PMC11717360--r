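# z-normalization, Savitzky-Golay smoothing, peak detection, cycle cutting.

test_that("z-normalization standardizes and is affine-invariant", {
  expect_equal(znormalize(c(-1, 0, 1)), c(-1, 0, 1))
  set.seed(71)
  x <- rnorm(500, mean = -2.3, sd = 0.4)
  z <- znormalize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(znormalize(3 * x - 7), z)      # affine invariance
  expect_equal(znormalize(c(NA, x))[-1], z)   # NAs ignored and propagated
  expect_error(znormalize(rep(2, 10)), "zero standard deviation")
  expect_error(znormalize(c(1, NA)), "at least 2")
})

test_that("Savitzky-Golay reproduces polynomials up to its order, edges included", {
  expect_equal(savgol_smooth(rep(2.5, 200)), rep(2.5, 200), tolerance = 1e-10)
  tt <- seq_len(300)
  pol <- 1 - 0.02 * tt + 3e-4 * tt^2 - 1e-6 * tt^3 + 2e-9 * tt^4 - 1e-12 * tt^5
  expect_equal(savgol_smooth(pol, order = 5, frame = 101), pol,
               tolerance = 1e-8)
  expect_error(savgol_smooth(rnorm(50), frame = 101), "smaller frame")
  expect_error(savgol_smooth(rnorm(200), frame = 100), "odd")
  expect_error(savgol_smooth(c(rnorm(199), NA)), "missing")
})

test_that("Savitzky-Golay equals a local least-squares fit at interior and edge positions", {
  set.seed(72)
  x <- cumsum(rnorm(260))
  sm <- savgol_smooth(x, order = 5, frame = 101)
  for (pos in c(1, 7, 50, 51, 130, 210, 254, 260)) {
    expect_equal(sm[pos], oracle_savgol_at(x, pos, 5, 101), tolerance = 1e-6)
  }
})

test_that("find_peaks handles the textbook cases", {
  # single interior maximum
  x <- c(0, 1, 2, 1, 0)
  pk <- find_peaks(x, min_prominence = 0.5)
  expect_identical(pk$index, 3L)
  expect_equal(pk$prominence, 2)
  # prominence below threshold is rejected
  expect_identical(nrow(find_peaks(c(0, 0.8, 0), min_prominence = 0.9)), 0L)
  # flat top reports its first sample
  x <- c(0, 1, 1, 1, 0)
  expect_identical(find_peaks(x)$index, 2L)
  # distance rule: the taller of two close peaks survives
  x <- numeric(100)
  x[30] <- 2; x[29] <- 1; x[31] <- 1
  x[60] <- 1.5; x[59] <- 0.8; x[61] <- 0.8
  got <- find_peaks(x, min_distance = 40, min_prominence = 0.9)
  expect_identical(got$index, 30L)
  # peaks exactly min_distance apart are both kept
  got2 <- find_peaks(x, min_distance = 30, min_prominence = 0.9)
  expect_identical(got2$index, c(30L, 60L))
})

test_that("find_peaks agrees with the brute-force oracle on random series", {
  for (seed in 1:60) {
    x <- random_walk_series(300, seed)
    md <- c(1, 10, 40)[seed %% 3 + 1]
    mp <- c(0, 0.5, 2)[seed %% 3 + 1] * sd(x) / 3
    got <- find_peaks(x, min_distance = md, min_prominence = mp)
    want <- oracle_find_peaks(x, min_distance = md, min_prominence = mp)
    expect_identical(got$index, want$index)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
  }
})

test_that("cycle count is monotone under threshold tightening", {
  for (seed in 1:10) {
    x <- znormalize(random_walk_series(900, seed + 100))
    n_by_prom <- sapply(c(0.5, 0.9, 1.3), function(p)
      nrow(find_peaks(x, min_distance = 40, min_prominence = p)))
    expect_true(all(diff(n_by_prom) <= 0))
    n_by_dist <- sapply(c(20, 40, 80), function(d)
      nrow(find_peaks(x, min_distance = d, min_prominence = 0.9)))
    expect_true(all(diff(n_by_dist) <= 0))
  }
})

test_that("extract_cycles computes durations and amplitudes between peaks", {
  # full cosine cycles starting and ending at troughs: peaks at 101, 301,
  # 501 (1-based), troughs midway, swing 3 z
  n <- 600
  x <- -2 + 1.5 * cos(2 * pi * (seq_len(n) - 101) / 200)
  pk <- find_peaks(x, min_distance = 40, min_prominence = 0.9)
  expect_identical(pk$index, c(101L, 301L, 501L))
  cyc <- extract_cycles(pk, x, epoch_length = 30)
  expect_identical(nrow(cyc), 2L)
  expect_equal(cyc$duration_min, c(100, 100))
  expect_equal(cyc$trough_epoch, c(200, 400))     # 0-based argmin between peaks
  expect_equal(cyc$descent_z, rep(-3, 2), tolerance = 1e-3)
  expect_equal(cyc$ascent_z, rep(3, 2), tolerance = 1e-3)
  expect_true(all(cyc$start_epoch < cyc$trough_epoch &
                    cyc$trough_epoch < cyc$end_epoch))
  expect_warning(out <- extract_cycles(pk[1, ], x), "fewer than 2 peaks")
  expect_identical(nrow(out), 0L)
})

test_that("durations use the original epoch grid when artifacts were dropped", {
  # peaks at positions 10 and 100 of the compacted series, but the original
  # indices have a 20-epoch artifact gap in between
  epoch_index <- c(0:49, 70:139)
  x <- -2 + cos(2 * pi * (seq_along(epoch_index) - 11) / 90)
  pk <- data.frame(index = c(11L, 101L), height = x[c(11, 101)],
                   prominence = c(2, 2))
  cyc <- extract_cycles(pk, x, epoch_index = epoch_index, epoch_length = 30)
  expect_identical(cyc$start_epoch, 10L)
  expect_identical(cyc$end_epoch, 120L)
  expect_equal(cyc$duration_min, (120 - 10) * 30 / 60)
})

test_that("planted smoothed series are recovered exactly peak-for-peak", {
  # noise-free planted series: the detector's peak stage finds the planted
  # peaks exactly, and K peaks give K - 1 cycles
  for (K in c(5L, 6L)) {
    sp <- synth_spec(n_cycles = K - 1, slope_noise_sd = 0, seed = K)
    ss <- synth_slope_series(sp)
    z <- znormalize(ss$series$slope_raw)
    pk <- find_peaks(z, min_distance = 40, min_prominence = 0.9)
    expect_identical(pk$index - 1L, as.integer(ss$truth$peak_epochs))
    cyc <- extract_cycles(pk, z, epoch_index = ss$series$epoch_index,
                          epoch_length = 30)
    expect_identical(nrow(cyc), K - 1L)
    expect_true(all(pmin(abs(cyc$descent_z), cyc$ascent_z) > 0.9))
  }
})

test_that("end-to-end detection on smoothed noisy series stays within a few epochs", {
  sp <- synth_spec(n_cycles = 4, seed = 17)
  ss <- synth_slope_series(sp)
  fc <- detect_fractal_cycles(ss$series)
  expect_identical(nrow(fc$cycles), 4L)
  expect_lte(max(abs(fc$peaks$epoch_index - ss$truth$peak_epochs)), 6)
  expect_true(all(fc$cycles$descent_z < 0 & fc$cycles$ascent_z > 0))
  # z-series invariant survives the pipeline
  expect_lt(abs(mean(fc$series$slope_z)), 1e-9)
  expect_lt(abs(sd(fc$series$slope_z) - 1), 1e-9)
})

test_that("overnight profile aggregates by cycle ordinal", {
  one <- data.frame(subject = "a", cycle = 1:3,
                    duration_min = c(80, 100, 90))
  prof <- overnight_profile(one)
  expect_equal(prof$duration_min_mean, c(80, 100, 90))
  two <- rbind(one, data.frame(subject = "b", cycle = 1,
                               duration_min = 100))
  prof2 <- overnight_profile(two)
  expect_equal(prof2$duration_min_mean[1], 90)
  expect_identical(prof2$n, c(2L, 1L, 1L))
})

test_that("a planted inverted-U cohort profile is recovered", {
  rows <- list()
  for (seed in 1:8) {
    sp <- synth_spec(n_cycles = 5, cycle_minutes_sd = 5, slope_noise_sd = 0.1,
                     seed = seed)
    ss <- synth_slope_series(sp)
    fc <- detect_fractal_cycles(ss$series)
    rows[[seed]] <- data.frame(subject = seed, fc$cycles)
  }
  prof <- overnight_profile(do.call(rbind, rows))
  planted <- 90 * fraccyc:::ordinal_profile(5)
  expect_lt(max(abs(prof$duration_min_mean - planted)), 5)
  # middle cycles longer than the first and last (inverted U)
  expect_gt(prof$duration_min_mean[3], prof$duration_min_mean[1])
  expect_gt(prof$duration_min_mean[3], prof$duration_min_mean[5])
})
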