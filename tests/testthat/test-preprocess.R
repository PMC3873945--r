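lay4 <- electrode_layout(4, 1)

test_that("common average reference removes the cross-channel mean", {
  c_const <- ecog_recording(matrix(5, 4, 100), 100, lay4)
  expect_equal(common_average_reference(c_const)$data, matrix(0, 4, 100))
  pm <- matrix(c(1, -1), 2, 50) * rep(runif(50), each = 2)
  rec2 <- ecog_recording(pm, 100, electrode_layout(2, 1))
  expect_equal(common_average_reference(rec2)$data, pm)
  set.seed(1)
  rnd <- ecog_recording(matrix(rnorm(4000), 4, 1000), 100, lay4)
  out <- common_average_reference(rnd)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # idempotent
  expect_equal(common_average_reference(out)$data, out$data, tolerance = 1e-12)
  expect_error(common_average_reference(
    ecog_recording(matrix(0, 1, 10), 100, electrode_layout(1, 1))), "2 channels")
})

test_that("common-average referencing removes the planted common-mode share", {
  traj <- generate_trajectory(30, 500, seed = 2)
  lay <- electrode_layout(4, 2)
  truth <- ground_truth(informative_channels = integer(0))
  cm_sd <- 3
  rec <- generate_ecog(traj, lay, truth, common_mode_sd = cm_sd, seed = 3)
  v_before <- mean(apply(rec$data, 1, var))
  v_after <- mean(apply(common_average_reference(rec)$data, 1, var))
  # variance bookkeeping: the shared component contributes cm_sd^2 per channel
  expect_equal(v_before - v_after, cm_sd^2, tolerance = 0.2 * cm_sd^2)
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  lay1 <- electrode_layout(1, 1)
  mk <- function(f) ecog_recording(matrix(sin(2 * pi * f * t), 1), fs, lay1)
  steady <- 3000:7000
  y100 <- bandpass(mk(100), c(90, 120))$data[1, steady]
  expect_equal(max(abs(y100)), 1, tolerance = 0.05)
  y10 <- bandpass(mk(10), c(90, 120))$data[1, steady]
  expect_lt(20 * log10(max(abs(y10))), -20)
  z <- bandpass(ecog_recording(matrix(0, 1, 1000), fs, lay1), c(90, 120))
  expect_equal(z$data, matrix(0, 1, 1000))
  expect_error(bandpass(mk(10), c(90, 260)), "Nyquist")
  expect_error(bandpass(mk(10), c(-1, 20)), "low")
})

test_that("envelope is a unit-gain nonnegative rectified smooth", {
  lay1 <- electrode_layout(1, 1)
  cst <- envelope(ecog_recording(matrix(2.5, 1, 500), 100, lay1))
  expect_equal(cst$data[1, ], rep(2.5, 500), tolerance = 1e-12)
  imp <- matrix(0, 1, 201); imp[101] <- 1
  ev <- envelope(ecog_recording(imp, 100, lay1), 0.1, 0.04)
  kern <- ecogpls:::gaussian_kernel(0.1, 0.04, 100)
  expect_equal(sum(ev$data), 1, tolerance = 1e-9)
  half <- (length(kern) - 1) / 2
  expect_equal(ev$data[1, (101 - half):(101 + half)], kern, tolerance = 1e-12)
  set.seed(3)
  rough <- envelope(ecog_recording(matrix(rnorm(1000), 1), 100, lay1))
  expect_true(all(rough$data >= 0))
})

test_that("sliding z-score is causal, standardizing, and guarded", {
  lay1 <- electrode_layout(1, 1)
  set.seed(5)
  n <- 1e5
  z <- sliding_zscore(ecog_recording(matrix(rnorm(n, 3, 2), 1), 500, lay1), 2)
  vals <- z$values[1, z$valid_from:n]
  expect_lt(abs(mean(vals)), 0.05)
  expect_lt(abs(sd(vals) - 1), 0.1)
  # constant input: zero output under the sigma floor
  zc <- sliding_zscore(ecog_recording(matrix(4, 1, 3000), 500, lay1), 2)
  expect_true(all(zc$values == 0))
  expect_true(all(is.finite(z$values[, z$valid_from:n])))
  # causality: perturbing the future never changes the present
  x <- rnorm(4000)
  a <- sliding_zscore(ecog_recording(matrix(x, 1), 500, lay1), 2)
  x2 <- x; x2[2501:4000] <- x2[2501:4000] + 50
  b <- sliding_zscore(ecog_recording(matrix(x2, 1), 500, lay1), 2)
  expect_identical(a$values[1, 1:2500], b$values[1, 1:2500])
})

test_that("feature tensor has the contracted shape, finiteness and scale invariance", {
  ds <- small_signal_dataset()
  few <- band_set(c("delta", "gamma3"), c(1.5, 90), c(4, 120))
  short <- ecog_recording(ds$recording$data[, 1:5000], 500, ds$recording$layout)
  ft <- compute_feature_tensor(short, few)
  expect_equal(dim(ft$values), c(8, 2, 5000))
  expect_true(all(is.finite(ft$values[, , ft$valid_from:5000])))
  # common rescaling of all channels cancels in the z-score
  scaled <- ecog_recording(short$data * 3.7, 500, short$layout)
  ft2 <- compute_feature_tensor(scaled, few)
  expect_equal(ft2$values, ft$values, tolerance = 1e-9)
  expect_error(compute_feature_tensor(
    ecog_recording(matrix(rnorm(1000), 1), 500, electrode_layout(1, 1)), few),
    "2 channels")
})

test_that("the fractionized band set yields one envelope series per 10-Hz band", {
  fb <- fractionized_bands()
  expect_equal(nrow(fb), 15)
  expect_equal(fb$high_hz[15], 150)
  ds <- small_signal_dataset()
  short <- ecog_recording(ds$recording$data[1:2, 1:3000], 500,
                          electrode_layout(2, 1))
  ft <- compute_feature_tensor(short, fb)
  expect_equal(dim(ft$values), c(2, 15, 3000))
})
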