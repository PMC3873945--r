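test_that("trajectory has the contracted shape, bounds and determinism", {
  traj <- generate_trajectory(20, 100, cycle_period_s = 5, jitter_sd = 0.1,
                              seed = 3)
  expect_equal(dim(traj$data), c(3, 2000))
  amp <- attr(traj, "amplitude")
  for (a in 1:3) {
    expect_lte(max(traj$data[a, ]), 2 * amp[a] + 1e-6)
    expect_gte(min(traj$data[a, ]), -1e-6 * amp[a])
  }
  expect_identical(traj$data,
                   generate_trajectory(20, 100, cycle_period_s = 5,
                                       jitter_sd = 0.1, seed = 3)$data)
  expect_error(generate_trajectory(-5, 100), "positive")
  expect_error(generate_trajectory(10, 100, cycle_period_s = 0), "positive")
})

test_that("zero jitter gives an exactly periodic trajectory", {
  fs <- 100; period <- 4
  traj <- generate_trajectory(24, fs, cycle_period_s = period, jitter_sd = 0,
                              seed = 1)
  x <- traj$data
  lag <- period * fs
  interior <- (lag + 50):(ncol(x) - lag - 50)
  expect_lt(max(abs(x[, interior] - x[, interior + lag])), 1e-9)
})

test_that("zero-weight coupling leaves band envelopes uncorrelated with the drive", {
  lay <- electrode_layout(2, 2)
  traj <- generate_trajectory(120, 500, seed = 5)
  truth <- ground_truth(informative_channels = integer(0))
  rec <- generate_ecog(traj, lay, truth, seed = 6)
  drive <- ecogpls:::kinematic_drive(traj)
  # gamma3 envelope of two channels vs the drive: null correlations stay small
  filt <- signal::butter(4, c(90, 120) / 250, type = "pass")
  for (ch in 1:2) {
    env <- ecogpls:::smooth_kernel(
      abs(ecogpls:::zero_phase_filter(filt, rec$data[ch, ], 20)),
      ecogpls:::gaussian_kernel(0.1, 0.04, 500))
    expect_lt(abs(cor(env, drive)), 0.15)
  }
})

test_that("an informative channel's planted band envelope tracks the lagged drive", {
  lay <- electrode_layout(2, 1)
  traj <- generate_trajectory(60, 500, seed = 8)
  truth <- ground_truth(informative_channels = 1L,
                        band_weights = c(gamma3 = 1), snr = 25,
                        coupling_lag_s = 0.09)
  rec <- generate_ecog(traj, lay, truth, common_mode_sd = 0, seed = 9)
  drive <- ecogpls:::kinematic_drive(traj)
  lag_n <- round(0.09 * 500)
  drive_lag <- c(rep(drive[1], lag_n), drive[seq_len(length(drive) - lag_n)])
  filt <- signal::butter(4, c(90, 120) / 250, type = "pass")
  env <- ecogpls:::smooth_kernel(
    abs(ecogpls:::zero_phase_filter(filt, rec$data[1, ], 20)),
    ecogpls:::gaussian_kernel(0.1, 0.04, 500))
  expect_gt(cor(env, drive_lag), 0.8)
  # the non-informative channel does not track it
  env2 <- ecogpls:::smooth_kernel(
    abs(ecogpls:::zero_phase_filter(filt, rec$data[2, ], 20)),
    ecogpls:::gaussian_kernel(0.1, 0.04, 500))
  expect_lt(abs(cor(env2, drive_lag)), 0.2)
})

test_that("carrier spectral power stays inside its band", {
  fs <- 500; n <- fs * 40
  set.seed(4)
  for (band in list(c(1.5, 4), c(50, 90), c(120, 150))) {
    x <- ecogpls:::bandlimited_noise(n, fs, band[1], band[2])
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE, taper = 0)
    inside <- sp$freq >= band[1] - 0.5 & sp$freq <= band[2] + 0.5
    expect_gt(sum(sp$spec[inside]) / sum(sp$spec), 0.95)
  }
})

test_that("dataset composition validates inputs and is deterministic", {
  cfg <- list(duration_s = 4, fs = 500, n_rows = 4L, n_cols = 2L,
              truth = ground_truth(informative_channels = 1:2), seed = 11L)
  ds1 <- make_dataset(cfg); ds2 <- make_dataset(cfg)
  expect_identical(ds1$recording$data, ds2$recording$data)
  expect_identical(ds1$trajectory$data, ds2$trajectory$data)
  expect_equal(ncol(ds1$recording$data), ncol(ds1$trajectory$data))
  expect_equal(ds1$recording$fs, ds1$trajectory$fs)
  # grid defaults mirror the 32-channel session; 5x3 15-channel also valid
  d32 <- make_dataset(list(duration_s = 2))
  expect_equal(dim(d32$recording$data), c(32, 1000))
  expect_equal(d32$recording$fs, 500)
  expect_equal(c(d32$recording$layout$n_rows, d32$recording$layout$n_cols), c(8, 4))
  d15 <- make_dataset(list(duration_s = 2, n_rows = 5L, n_cols = 3L,
                           truth = ground_truth(informative_channels = 1:2)))
  expect_equal(nrow(d15$recording$data), 15)
  expect_error(make_dataset(list(bogus = 1)), "unknown config")
  expect_error(ground_truth(coupling_lag_s = 0.7), "0.6")
  expect_error(make_dataset(list(duration_s = 2,
                                 truth = ground_truth(informative_channels = 99L))),
               "absent from layout")
})

test_that("dataset container round-trips losslessly", {
  ds <- make_dataset(list(duration_s = 3, fs = 500, n_rows = 2L, n_cols = 2L,
                          truth = ground_truth(informative_channels = 1L,
                                               band_weights = c(gamma3 = 1)),
                          seed = 13L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_lt(max(abs(back$recording$data - ds$recording$data)) /
              max(abs(ds$recording$data)), 1e-12)
  expect_lt(max(abs(back$trajectory$data - ds$trajectory$data)) /
              max(abs(ds$trajectory$data)), 1e-12)
  expect_equal(back$recording$layout$table, ds$recording$layout$table)
  expect_equal(back$truth$informative_channels, ds$truth$informative_channels)
  expect_equal(back$truth$snr, ds$truth$snr)
  expect_equal(as.data.frame(back$bands), as.data.frame(ds$bands))
  expect_equal(back$seed, ds$seed)
})
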