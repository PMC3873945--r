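#' ECoG recording and trajectory containers
#'
#' `ecog_recording()` wraps a channels x samples potential matrix with its
#' sampling rate and electrode layout; `trajectory()` wraps a 3 x samples
#' hand-position matrix (x, y, z) on the same clock.
#'
#' @param data numeric matrix, channels x samples (recording) or
#'   3 x samples (trajectory).
#' @param fs sampling rate in Hz.
#' @param layout an [electrode_layout()] whose channel count matches
#'   `nrow(data)`.
#' @return an `ecog_recording` / `trajectory` object.
#' @export
ecog_recording <- function(data, fs, layout) {
  check_scalar_pos(fs, "fs")
  if (!is.matrix(data) || !is.numeric(data)) stop_invalid("data must be a numeric matrix")
  if (anyNA(data)) stop_invalid("recording contains missing values")
  if (nrow(data) != nrow(layout$table))
    stop_invalid("data has ", nrow(data), " rows but layout has ",
                 nrow(layout$table), " channels")
  structure(list(data = data, fs = fs, layout = layout), class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @rdname ecog_recording
#' @export
trajectory <- function(data, fs) {
  check_scalar_pos(fs, "fs")
  if (!is.matrix(data) || nrow(data) != 3L)
    stop_invalid("trajectory data must be a 3 x samples matrix")
  if (anyNA(data)) stop_invalid("trajectory contains missing values")
  rownames(data) <- c("x", "y", "z")
  structure(list(data = data, fs = fs), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> 3 x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}
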