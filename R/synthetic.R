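#' Ground truth for a synthetic dataset
#'
#' Encodes which channels carry kinematic information and how: each
#' informative channel's envelope in each weighted band is linearly coupled
#' to a standardized kinematic drive delayed by `coupling_lag_s`. The
#' signal-to-noise ratio `snr` is the ratio of coupled-envelope variance to
#' the variance of the stochastic envelope fluctuations every channel has.
#'
#' @param informative_channels integer channel ids (may be empty for a null
#'   dataset).
#' @param band_weights named nonnegative weights, names drawn from the band
#'   set used at generation (e.g. `c(gamma3 = 1, gamma4 = 0.7, delta = 0.5)`).
#' @param coupling_lag_s envelope delay behind the kinematics, seconds in
#'   \[0, 0.6\].
#' @param snr coupled-to-noise envelope variance ratio on a weight-1 band.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(informative_channels = integer(0),
                         band_weights = c(gamma3 = 1, gamma4 = 0.7, delta = 0.5),
                         coupling_lag_s = 0.09, snr = 10) {
  if (length(band_weights) && (is.null(names(band_weights)) || any(names(band_weights) == "")))
    stop_invalid("band_weights must be a named vector")
  if (any(band_weights < 0)) stop_invalid("band weights must be nonnegative")
  if (!is.numeric(coupling_lag_s) || coupling_lag_s < 0 || coupling_lag_s > 0.6)
    stop_invalid("coupling_lag_s must lie in [0, 0.6] seconds")
  if (snr < 0) stop_invalid("snr must be nonnegative")
  structure(list(informative_channels = as.integer(informative_channels),
                 band_weights = band_weights,
                 coupling_lag_s = coupling_lag_s, snr = snr),
            class = "ground_truth")
}

#' Pseudo-periodic 3-D reach trajectory
#'
#' Emulates a monkey performing reach-grasp-pull-release cycles continuously
#' for several minutes: each coordinate follows a raised-cosine reach-and-
#' return profile per cycle, with per-cycle amplitude and period jitter and
#' slight phase offsets between the x, y, z coordinates, low-pass smoothed.
#' With `jitter_sd = 0` the trajectory is exactly periodic.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param cycle_period_s nominal reach cycle period (s).
#' @param jitter_sd fractional s.d. of per-cycle period and amplitude jitter.
#' @param amplitude peak excursion per axis (same units as positions).
#' @param axis_phase per-axis phase offsets (cycle fraction).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return a [trajectory()].
#' @export
generate_trajectory <- function(duration_s, fs, cycle_period_s = 5,
                                jitter_sd = 0.1,
                                amplitude = c(8, 6, 4),
                                axis_phase = c(0, 0.02, 0.04),
                                seed = 1L) {
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(fs, "fs")
  check_scalar_pos(cycle_period_s, "cycle_period_s")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be nonnegative")
  n <- round(duration_s * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_cyc <- ceiling(duration_s / cycle_period_s * 4) + 2L
  # jitter clipped so every coordinate stays within [0, 2 * amplitude]
  periods <- cycle_period_s * pmin(pmax(1 + stats::rnorm(n_cyc, 0, jitter_sd), 0.3), 2)
  bounds <- cumsum(c(0, periods))
  amps <- matrix(pmin(pmax(1 + stats::rnorm(n_cyc * 3L, 0, jitter_sd), 0.2), 2),
                 n_cyc, 3L)
  tt <- (seq_len(n) - 1L) / fs
  ci <- findInterval(tt, bounds)
  phase <- (tt - bounds[ci]) / periods[ci]
  pos <- vapply(1:3, function(a) {
    ph <- (phase + axis_phase[a]) %% 1
    amplitude[a] * amps[ci, a] * 0.5 * (1 - cos(2 * pi * ph))
  }, numeric(n))
  kern <- gaussian_kernel(0.2, 0.05, fs)
  pos <- apply(pos, 2L, smooth_kernel, kernel = kern)
  traj <- trajectory(t(pos), fs)
  attr(traj, "amplitude") <- amplitude
  traj
}

# Scalar kinematic drive: standardized sum of the standardized position
# coordinates and the smoothed hand speed. Any functional the lagged linear
# decoder can recover would do; this one ties every band envelope to both
# where the hand is and how fast it moves.
kinematic_drive <- function(traj) {
  pos <- t(traj$data)
  vel <- apply(pos, 2L, function(x) c(0, diff(x)) * traj$fs)
  speed <- sqrt(rowSums(vel^2))
  speed <- smooth_kernel(speed, gaussian_kernel(0.2, 0.05, traj$fs))
  standardize(standardize(pos[, 1]) + standardize(pos[, 2]) +
              standardize(pos[, 3]) + standardize(speed))
}

#' Synthetic ECoG with planted kinematic coupling
#'
#' Each channel is a sum over bands of a band-limited noise carrier
#' multiplied by a slowly varying envelope, plus broadband noise and a
#' common-mode signal shared by all channels. On informative channels the
#' envelope of each weighted band is `1 + weight * sqrt(snr) * sigma_env *
#' drive(t - lag)`; every channel-band additionally carries stochastic
#' envelope fluctuations of s.d. `sigma_env`, so `snr` is the planted
#' coupled-to-noise envelope variance ratio at weight 1. Carriers are
#' synthesized in the frequency domain, so their power is confined to the
#' band.
#'
#' @param traj a [trajectory()] on the target clock.
#' @param layout an [electrode_layout()].
#' @param truth a [ground_truth()]; `informative_channels` must exist in the
#'   layout and `band_weights` names in `bands`.
#' @param fs sampling rate in Hz; must match the trajectory.
#' @param bands [band_set()] whose envelopes are generated.
#' @param common_mode_sd s.d. of the shared common-mode signal (0 disables).
#' @param broadband_sd s.d. of per-channel wideband noise.
#' @param sigma_env s.d. of stochastic envelope fluctuations (baseline 1).
#' @param seed integer RNG seed.
#' @return an [ecog_recording()].
#' @export
generate_ecog <- function(traj, layout, truth, fs = traj$fs,
                          bands = physiological_bands(),
                          common_mode_sd = 1, broadband_sd = 0.5,
                          sigma_env = 0.2, seed = 1L) {
  stopifnot(inherits(traj, "trajectory"), inherits(truth, "ground_truth"))
  if (fs != traj$fs) stop_invalid("fs (", fs, ") does not match trajectory fs (", traj$fs, ")")
  validate_band_set(bands, fs)
  bad <- setdiff(truth$informative_channels, layout_channels(layout))
  if (length(bad)) stop_invalid("informative channels absent from layout: ",
                                paste(bad, collapse = ", "))
  badb <- setdiff(names(truth$band_weights), bands$name)
  if (length(badb)) stop_invalid("band_weights name(s) not in band set: ",
                                 paste(badb, collapse = ", "))
  n <- ncol(traj$data)
  channels <- layout_channels(layout)
  lag_n <- round(truth$coupling_lag_s * fs)
  drive <- kinematic_drive(traj)
  drive_lag <- if (lag_n > 0) c(rep(drive[1L], lag_n), drive[seq_len(n - lag_n)]) else drive
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dat <- matrix(0, length(channels), n)
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    x <- broadband_sd * stats::rnorm(n)
    for (b in seq_len(nrow(bands))) {
      carrier <- bandlimited_noise(n, fs, bands$low_hz[b], bands$high_hz[b])
      w <- 0
      if (ch %in% truth$informative_channels) {
        bn <- bands$name[b]
        if (bn %in% names(truth$band_weights))
          w <- truth$band_weights[[bn]] * sqrt(truth$snr) * sigma_env
      }
      env <- 1 + w * drive_lag + sigma_env * bandlimited_noise(n, fs, 0.02, 1)
      # amplitude envelopes are physical: floored at a small positive value
      x <- x + carrier * pmax(env, 0.05)
    }
    dat[ci, ] <- x
  }
  if (common_mode_sd > 0)
    dat <- sweep(dat, 2L, common_mode_sd * bandlimited_noise(n, fs, 0.02, 30), "+")
  ecog_recording(dat, fs, layout)
}

#' Compose a complete synthetic dataset
#'
#' Generates a trajectory and a matching ECoG recording from one config
#' list, storing the seed and ground truth for recovery tests. Defaults
#' emulate the 32-channel session: a 4-column x 8-row grid, 700 s at
#' 500 Hz, ~5 s reach cycles.
#'
#' @param config named list; recognized fields (with defaults):
#'   `duration_s` (700), `fs` (500), `n_rows` (8), `n_cols` (4),
#'   `cycle_period_s` (5), `jitter_sd` (0.1), `bands`
#'   (physiological_bands()), `truth` (a [ground_truth()]),
#'   `common_mode_sd` (1), `broadband_sd` (0.5), `sigma_env` (0.2),
#'   `seed` (1).
#' @return a `synthetic_dataset`: list with `recording`, `trajectory`,
#'   `truth`, `bands`, `seed`, `config`.
#' @export
make_dataset <- function(config = list()) {
  defaults <- list(duration_s = 700, fs = 500, n_rows = 8L, n_cols = 4L,
                   cycle_period_s = 5, jitter_sd = 0.1,
                   bands = physiological_bands(),
                   truth = ground_truth(informative_channels = 1:10),
                   common_mode_sd = 1, broadband_sd = 0.5, sigma_env = 0.2,
                   seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop_invalid("unknown config field(s): ",
                                    paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  layout <- electrode_layout(cfg$n_rows, cfg$n_cols)
  traj <- generate_trajectory(cfg$duration_s, cfg$fs, cfg$cycle_period_s,
                              cfg$jitter_sd, seed = cfg$seed)
  rec <- generate_ecog(traj, layout, cfg$truth, fs = cfg$fs, bands = cfg$bands,
                       common_mode_sd = cfg$common_mode_sd,
                       broadband_sd = cfg$broadband_sd,
                       sigma_env = cfg$sigma_env,
                       seed = cfg$seed + 1000L)
  structure(list(recording = rec, trajectory = traj, truth = cfg$truth,
                 bands = cfg$bands, seed = cfg$seed, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> seed %d, %d channels, %.0f s @ %g Hz, %d informative channel(s)\n",
              x$seed, nrow(x$recording$data), ncol(x$recording$data) / x$recording$fs,
              x$recording$fs, length(x$truth$informative_channels)))
  invisible(x)
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
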