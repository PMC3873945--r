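# Butterworth band-pass design in second-order sections (biquad cascade).
#
# The transfer-function (b, a) form of an 8-pole band-pass with a 1.5-Hz
# edge at 500 Hz clusters all roots near z = 1 and loses several digits;
# cascaded biquads keep each factor well conditioned. Poles are computed
# analytically (analog prototype -> band-pass transform -> bilinear), never
# by polynomial root finding.

butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  stopifnot(order >= 1, low_hz > 0, low_hz < high_hz, high_hz < fs / 2)
  # prewarped analog edge frequencies
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1; w0 <- sqrt(w1 * w2)
  # analog low-pass prototype poles (cutoff 1, left half-plane)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each prototype pole yields a conjugate-free pair
  bp <- unlist(lapply(proto, function(p) {
    disc <- sqrt((bw * p)^2 - 4 * w0^2)
    c((bw * p + disc) / 2, (bw * p - disc) / 2)
  }))
  z <- (1 + bp / (2 * fs)) / (1 - bp / (2 * fs))   # bilinear transform
  # one biquad per conjugate pole pair; zeros at z = 1 and z = -1
  ppos <- z[Im(z) > 1e-9]
  preal <- Re(z[abs(Im(z)) <= 1e-9])
  sections <- c(
    lapply(ppos, function(p) list(b = c(1, 0, -1),
                                  a = c(1, -2 * Re(p), Mod(p)^2))),
    if (length(preal) >= 2)
      lapply(seq_len(length(preal) %/% 2), function(i) {
        pr <- preal[c(2 * i - 1, 2 * i)]
        list(b = c(1, 0, -1), a = c(1, -sum(pr), prod(pr)))
      }))
  if (length(sections) != order)
    stop_invalid("band-pass pole pairing failed for band ", low_hz, "-", high_hz, " Hz")
  # normalize to unit gain at the band's geometric-center frequency
  wc <- 2 * pi * sqrt(low_hz * high_hz) / fs
  zc <- exp(1i * wc)
  h <- prod(vapply(sections, function(s)
    (sum(s$b * zc^(0:-2))) / (sum(s$a * zc^(0:-2))), complex(1)))
  sections[[1]]$b <- sections[[1]]$b / Mod(h)
  sections
}

sos_filter <- function(sections, x) {
  for (s in sections) x <- signal::filter(s$b, s$a, x)
  x
}

# Zero-phase application of a biquad cascade: reflective padding, full
# cascade forward, full cascade backward.
zero_phase_sos <- function(sections, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- sos_filter(sections, xp)
  y <- rev(sos_filter(sections, rev(y)))
  y[(pad + 1L):(pad + n)]
}
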