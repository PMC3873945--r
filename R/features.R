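#' Lag specification for the decoder
#'
#' The decoder reads the feature tensor at `n_lags` equally spaced lags
#' `step_s, 2*step_s, ..., n_lags*step_s` strictly before each predicted
#' sample. The default (30 ms step, 20 lags) tiles the 0.6 s interval
#' before t.
#'
#' @param step_s lag step in seconds.
#' @param n_lags number of lags.
#' @return a `lag_spec`.
#' @export
lag_spec <- function(step_s = 0.03, n_lags = 20L) {
  check_scalar_pos(step_s, "step_s")
  if (n_lags < 1) stop_invalid("n_lags must be >= 1")
  structure(list(step_s = step_s, n_lags = as.integer(n_lags),
                 span_s = step_s * n_lags), class = "lag_spec")
}

#' Lag-embedded design matrix and targets
#'
#' Builds one predictor row per retained time t on the stride grid: the
#' feature value S_norm(i, j, t - k*step) for every channel i, band j and
#' lag k = 1..n_lags, paired with the hand position at t. Times before the
#' normalization warm-up plus the lag span are dropped, so every row is
#' fully valid and strictly causal.
#'
#' @param feat a `feature_tensor` from [compute_feature_tensor()].
#' @param traj a [trajectory()] on the same clock.
#' @param lags a [lag_spec()].
#' @param stride_s spacing of retained times in seconds (default: one row
#'   per lag step).
#' @return a `design_matrix`: list with `X` (rows x columns), `Y` (rows x 3),
#'   `index` (data.frame column, channel, band, lag mapping every column),
#'   `times_s`, `fs`, `lags`, `band_set`, `layout`.
#' @export
lag_embed <- function(feat, traj, lags = lag_spec(), stride_s = lags$step_s) {
  stopifnot(inherits(feat, "feature_tensor"), inherits(traj, "trajectory"))
  if (feat$fs != traj$fs) stop_invalid("feature tensor and trajectory sampling rates differ")
  n <- dim(feat$values)[3]
  if (ncol(traj$data) != n) stop_invalid("feature tensor and trajectory lengths differ")
  step_n <- round(lags$step_s * feat$fs)
  if (step_n < 1) stop_invalid("lag step shorter than one sample")
  stride_n <- round(stride_s * feat$fs)
  if (stride_n < 1) stop_invalid("stride shorter than one sample")
  t_min <- feat$valid_from + lags$n_lags * step_n
  tgrid <- seq.int(t_min, n, by = stride_n)
  if (length(tgrid) == 0L) stop_insufficient("no retained times after warm-up")
  channels <- layout_channels(feat$layout)
  n_ch <- length(channels); n_b <- nrow(feat$band_set)
  index <- data.frame(
    column = seq_len(n_ch * n_b * lags$n_lags),
    channel = rep(channels, each = n_b * lags$n_lags),
    band = rep(rep(feat$band_set$name, each = lags$n_lags), times = n_ch),
    lag = rep(seq_len(lags$n_lags), times = n_ch * n_b))
  X <- matrix(0, length(tgrid), nrow(index))
  col <- 1L
  for (i in seq_len(n_ch)) for (b in seq_len(n_b)) for (k in seq_len(lags$n_lags)) {
    X[, col] <- feat$values[i, b, tgrid - k * step_n]
    col <- col + 1L
  }
  structure(list(X = X, Y = t(traj$data[, tgrid, drop = FALSE]),
                 index = index, times_s = (tgrid - 1L) / feat$fs,
                 fs = feat$fs, lags = lags, band_set = feat$band_set,
                 layout = feat$layout),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d rows x %d columns (%d channels x %d bands x %d lags)\n",
              nrow(x$X), ncol(x$X), length(unique(x$index$channel)),
              length(unique(x$index$band)), x$lags$n_lags))
  invisible(x)
}

#' Contiguous temporal train/test split
#'
#' The first `train_s` seconds of retained rows are used for fitting, the
#' following `test_s` seconds for evaluation; no row is in both and the
#' blocks do not overlap in time, so lag windows never leak across the
#' boundary in the direction that matters (test rows only ever look back).
#'
#' @param design a `design_matrix` from [lag_embed()].
#' @param train_s,test_s segment lengths in seconds.
#' @return list with `train` and `test`, each a `design_matrix`.
#' @export
split_train_test <- function(design, train_s = 500, test_s = 200) {
  stopifnot(inherits(design, "design_matrix"))
  t0 <- design$times_s[1]
  total <- design$times_s[length(design$times_s)] - t0
  if (total < train_s + test_s)
    stop_insufficient("retained data spans ", round(total, 1),
                      " s < train_s + test_s = ", train_s + test_s, " s")
  in_train <- design$times_s < t0 + train_s
  in_test <- !in_train & design$times_s < t0 + train_s + test_s
  list(train = subset_rows(design, which(in_train)),
       test = subset_rows(design, which(in_test)))
}

subset_rows <- function(design, rows) {
  design$X <- design$X[rows, , drop = FALSE]
  design$Y <- design$Y[rows, , drop = FALSE]
  design$times_s <- design$times_s[rows]
  design
}

#' Restrict a design matrix to a channel or band subset
#'
#' Keeps exactly the columns whose channel (resp. band) belongs to the
#' requested set, preserving column order and updating the column index.
#'
#' @param design a `design_matrix`.
#' @param channels channel ids to keep.
#' @return the restricted `design_matrix`.
#' @export
restrict_channels <- function(design, channels) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(channels) == 0L) stop_invalid("channel set must be non-empty")
  known <- unique(design$index$channel)
  bad <- setdiff(channels, known)
  if (length(bad)) stop_invalid("unknown channel id(s): ", paste(bad, collapse = ", "))
  restrict_cols(design, design$index$channel %in% channels)
}

#' @rdname restrict_channels
#' @param bands band names to keep.
#' @export
restrict_bands <- function(design, bands) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(bands) == 0L) stop_invalid("band set must be non-empty")
  bad <- setdiff(bands, unique(design$index$band))
  if (length(bad)) stop_invalid("unknown band(s): ", paste(bad, collapse = ", "))
  restrict_cols(design, design$index$band %in% bands)
}

restrict_cols <- function(design, keep) {
  design$X <- design$X[, keep, drop = FALSE]
  design$index <- design$index[keep, , drop = FALSE]
  design$index$column <- seq_len(nrow(design$index))
  rownames(design$index) <- NULL
  design
}
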