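#' Pipeline configuration defaults
#'
#' One list drives every stage downstream of the generator: band set, lag
#' embedding, train/test split, and the latent-count policy. `n_latent =
#' NULL` selects the count by ten-fold cross-validated PRESS on the full
#' training design (plateau rule, capped at `latent_cap`); a number fixes
#' it directly.
#'
#' @param ... overrides for the defaults listed below.
#' @return a named list: `bands` (NULL = dataset's band set), `lags`
#'   ([lag_spec()]), `stride_s` (0.03), `train_s` (500), `test_s` (200),
#'   `n_latent` (NULL), `max_latent` (20), `latent_cap` (20),
#'   `plateau_tol` (0.01), `k_folds` (10), `zscore_window_s` (2),
#'   `smooth_width_s` (0.1), `smooth_sigma_s` (0.04).
#' @export
decoding_config <- function(...) {
  cfg <- list(bands = NULL, lags = lag_spec(), stride_s = 0.03,
              train_s = 500, test_s = 200,
              n_latent = NULL, max_latent = 20L, latent_cap = 20L,
              plateau_tol = 0.01, k_folds = 10L,
              zscore_window_s = 2, smooth_width_s = 0.1, smooth_sigma_s = 0.04)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_invalid("unknown config field(s): ",
                                    paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Prepare a dataset for decoding
#'
#' Runs preprocessing (CAR, band-pass, envelope, causal z-score), lag
#' embedding and the contiguous train/test split, then caches the centered
#' crossproduct matrices of the training design. Because centering and
#' column subsetting commute, every channel- or band-restricted model can
#' afterwards be fitted from a submatrix of the cached crossproducts
#' without touching the raw design again — which is what makes exhaustive
#' single-electrode ranking affordable.
#'
#' @param dataset a `synthetic_dataset` from [make_dataset()] (or any list
#'   with `recording`, `trajectory`, `bands`).
#' @param config a [decoding_config()].
#' @return a `decoder_context`.
#' @export
prepare_decoding <- function(dataset, config = decoding_config()) {
  bands <- if (is.null(config$bands)) dataset$bands else config$bands
  feat <- compute_feature_tensor(dataset$recording, bands,
                                 smooth_width_s = config$smooth_width_s,
                                 smooth_sigma_s = config$smooth_sigma_s,
                                 zscore_window_s = config$zscore_window_s)
  design <- lag_embed(feat, dataset$trajectory, config$lags, config$stride_s)
  rm(feat); gc(FALSE)
  sp <- split_train_test(design, config$train_s, config$test_s)
  rm(design); gc(FALSE)
  new_decoder_context(sp$train, sp$test, config)
}

new_decoder_context <- function(train, test, config) {
  x_mean <- colMeans(train$X); y_mean <- colMeans(train$Y)
  Xc <- sweep(train$X, 2L, x_mean)
  Cxx <- crossprod(Xc)
  Cxy <- crossprod(Xc, sweep(train$Y, 2L, y_mean))
  rm(Xc); gc(FALSE)
  structure(list(train = train, test = test, config = config,
                 x_mean = x_mean, y_mean = y_mean, Cxx = Cxx, Cxy = Cxy),
            class = "decoder_context")
}

#' @export
print.decoder_context <- function(x, ...) {
  cat(sprintf("<decoder_context> %d train / %d test rows, %d feature columns\n",
              nrow(x$train$X), nrow(x$test$X), ncol(x$train$X)))
  invisible(x)
}

# Resolve the latent count for a context: explicit config value, or PRESS
# CV on the full training design (run once and memoized on the context's
# environmentless list via attribute return).
context_n_latent <- function(ctx) {
  if (!is.null(ctx$config$n_latent)) return(as.integer(ctx$config$n_latent))
  curve <- cross_validate(ctx$train$X, ctx$train$Y,
                          max_latent = ctx$config$max_latent,
                          k_folds = ctx$config$k_folds)
  select_n_latent(curve, ctx$config$plateau_tol, ctx$config$latent_cap)
}

# Fit a model restricted to a set of design columns, from the cached
# crossproducts. n_latent is capped by the restricted rank bound.
fit_restricted <- function(ctx, cols, n_latent) {
  A <- min(n_latent, length(cols), nrow(ctx$train$X) - 1L)
  all_cols <- length(cols) == ncol(ctx$train$X) && all(cols == seq_along(cols))
  core <- if (all_cols) pls_kernel_core(ctx$Cxx, ctx$Cxy, A)
  else pls_kernel_core(ctx$Cxx[cols, cols, drop = FALSE],
                       ctx$Cxy[cols, , drop = FALSE], A)
  idx <- ctx$train$index[cols, , drop = FALSE]
  idx$column <- seq_len(nrow(idx))
  new_pls_model(core, ctx$x_mean[cols], ctx$y_mean, idx)
}

# Fit on a column subset and evaluate on the held-out test segment.
eval_restricted <- function(ctx, cols, n_latent) {
  model <- fit_restricted(ctx, cols, n_latent)
  Xte <- if (length(cols) == ncol(ctx$test$X) && all(cols == seq_along(cols)))
    ctx$test$X else ctx$test$X[, cols, drop = FALSE]
  yhat <- predict(model, Xte)
  r2 <- r_squared(ctx$test$Y, yhat)
  list(model = model, r2 = r2)
}

cols_for <- function(ctx, channels = NULL, bands = NULL) {
  idx <- ctx$train$index
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(channels)) keep <- keep & idx$channel %in% channels
  if (!is.null(bands)) keep <- keep & idx$band %in% bands
  which(keep)
}

#' Fit and evaluate the full decoder on a prepared context
#'
#' @param ctx a `decoder_context` from [prepare_decoding()].
#' @param n_latent latent count; defaults to the context's policy.
#' @return list with `model`, `r2` (held-out, per axis + mean), `n_latent`.
#' @export
decode_full <- function(ctx, n_latent = NULL) {
  if (is.null(n_latent)) n_latent <- context_n_latent(ctx)
  out <- eval_restricted(ctx, seq_len(ncol(ctx$train$X)), n_latent)
  out$n_latent <- out$model$n_latent
  out
}
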