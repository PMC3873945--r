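#' Frequency band sets
#'
#' A band set is an ordered table of named frequency intervals used to
#' decompose ECoG into band-envelope features. Two canonical sets are
#' provided: the nine physiological bands commonly tied to motor activity
#' (delta 1.5-4, theta 4-8, alpha 8-14, beta1 14-20, beta2 20-30,
#' gamma1 30-50, gamma2 50-90, gamma3 90-120, gamma4 120-150 Hz), and a
#' uniform "fractionized" set of 10-Hz-wide bands covering 0-150 Hz used to
#' test whether physiological band edges matter.
#'
#' @param name,low_hz,high_hz vectors defining each band (Hz).
#' @return a `band_set`: a data.frame with columns `name`, `low_hz`, `high_hz`.
#' @examples
#' physiological_bands()
#' fractionized_bands()
#' @export
band_set <- function(name, low_hz, high_hz) {
  if (anyDuplicated(name)) stop_invalid("band names must be unique")
  if (length(name) == 0L) stop_invalid("band set must contain at least one band")
  if (any(!is.finite(low_hz)) || any(!is.finite(high_hz)) ||
      any(low_hz <= 0) || any(low_hz >= high_hz))
    stop_invalid("each band needs 0 < low_hz < high_hz")
  structure(data.frame(name = as.character(name),
                       low_hz = as.numeric(low_hz),
                       high_hz = as.numeric(high_hz),
                       stringsAsFactors = FALSE),
            class = c("band_set", "data.frame"))
}

#' @rdname band_set
#' @export
physiological_bands <- function() {
  band_set(
    name = c("delta", "theta", "alpha", "beta1", "beta2",
             "gamma1", "gamma2", "gamma3", "gamma4"),
    low_hz  = c(1.5, 4, 8, 14, 20, 30, 50, 90, 120),
    high_hz = c(4, 8, 14, 20, 30, 50, 90, 120, 150))
}

#' @rdname band_set
#' @param width_hz band width in Hz for the uniform set.
#' @param max_hz upper edge of the covered range.
#' @export
fractionized_bands <- function(width_hz = 10, max_hz = 150) {
  lows <- seq(0, max_hz - width_hz, by = width_hz)
  # a 0-Hz lower edge is replaced by a small positive edge so the band-pass
  # design stays well posed
  lo <- pmax(lows, 0.5)
  band_set(name = sprintf("b%03d_%03d", lows, lows + width_hz),
           low_hz = lo, high_hz = lows + width_hz)
}

is_band_set <- function(x) inherits(x, "band_set")

validate_band_set <- function(bands, fs = NULL) {
  if (!is_band_set(bands)) stop_invalid("not a band_set")
  if (!is.null(fs) && any(bands$high_hz >= fs / 2))
    stop_invalid("band edge at or above Nyquist frequency (fs/2 = ", fs / 2, " Hz)")
  invisible(bands)
}
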