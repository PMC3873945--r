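# Internal helpers shared across the pipeline.

stop_invalid <- function(...) {
  stop(structure(class = c("ecogpls_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_insufficient <- function(...) {
  stop(structure(class = c("ecogpls_insufficient_data", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(name, " must be a positive finite scalar")
  invisible(x)
}

#' @noRd
standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# Truncated unit-area Gaussian kernel: total width `width_s`, std `sigma_s`.
gaussian_kernel <- function(width_s, sigma_s, fs) {
  check_scalar_pos(width_s, "width_s")
  check_scalar_pos(sigma_s, "sigma_s")
  half <- max(1L, round(width_s * fs / 2))
  k <- stats::dnorm(seq(-half, half), mean = 0, sd = sigma_s * fs)
  k / sum(k)
}

# Symmetric FIR smoothing with edge-replication padding so that constant
# inputs pass through unchanged (DC gain exactly 1).
smooth_kernel <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2L)
  as.numeric(y[(half + 1L):(half + n)])
}

# Band-limited Gaussian noise via frequency-domain synthesis: unit variance,
# (numerically) zero power outside [low_hz, high_hz].
bandlimited_noise <- function(n, fs, low_hz, high_hz) {
  freqs <- seq(0, n - 1) * fs / n
  # two-sided support (positive frequencies and their aliases)
  f_fold <- pmin(freqs, fs - freqs)
  keep <- f_fold >= low_hz & f_fold <= high_hz
  spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  spec[!keep] <- 0 + 0i
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  (x - mean(x)) / s
}
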