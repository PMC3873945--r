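#' Frequency-band contribution of a fitted decoder
#'
#' For each output axis, the contribution of band j is the sum of absolute
#' model weights over all channels and lags in that band, normalized by the
#' total absolute weight, expressed as a percentage. Per axis the
#' contributions are nonnegative and sum to 100.
#'
#' @param model a `pls_model` fitted on a `design_matrix` (so the column
#'   bijection is available).
#' @return a `contribution_table`: data.frame with `band`, `x`, `y`, `z`,
#'   `mean` (percent).
#' @export
band_contribution <- function(model) {
  if (is.null(model$index)) stop_invalid("model was not fitted on a design_matrix")
  if (all(model$B == 0)) stop_invalid("all model weights are zero; contribution undefined")
  bands <- unique(model$index$band)
  absw <- abs(model$B)
  per_axis <- vapply(seq_len(ncol(absw)), function(a) {
    s <- vapply(bands, function(b)
      sum(absw[model$index$band == b, a]), numeric(1))
    100 * s / sum(s)
  }, numeric(length(bands)))
  tab <- data.frame(band = bands,
                    x = per_axis[, 1], y = per_axis[, 2], z = per_axis[, 3],
                    mean = rowMeans(per_axis))
  rownames(tab) <- NULL
  structure(tab, class = c("contribution_table", "data.frame"))
}

#' Per-band decoding performance
#'
#' Refits the decoder restricted to each frequency band individually (all
#' channels, all lags within the band) and evaluates held-out R-squared,
#' quantifying how much each band alone can decode.
#'
#' @param dataset dataset or prepared `decoder_context`.
#' @param config a [decoding_config()].
#' @param n_latent latent count; defaults to the context policy.
#' @return data.frame with `band`, `r2_x`, `r2_y`, `r2_z`, `r2_mean`, one
#'   row per band in band-set order.
#' @export
per_band_decoding <- function(dataset, config = decoding_config(),
                              n_latent = NULL) {
  ctx <- as_decoder_context(dataset, config)
  if (is.null(n_latent)) n_latent <- context_n_latent(ctx)
  bands <- unique(ctx$train$index$band)
  rows <- lapply(bands, function(b) {
    r2 <- eval_restricted(ctx, cols_for(ctx, bands = b), n_latent)$r2
    data.frame(band = b, r2_x = r2$per_axis[[1]], r2_y = r2$per_axis[[2]],
               r2_z = r2$per_axis[[3]], r2_mean = r2$mean,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Map per-channel scores onto the electrode grid
#'
#' Places each channel's score at its (row, col) grid position, giving the
#' spatial performance map (column 1 = central-sulcus side, row 1 = medial
#' edge). Grid cells without a channel are `NA`.
#'
#' @param scores data.frame with `channel` and a score column.
#' @param layout an [electrode_layout()] covering exactly the scored
#'   channels.
#' @param value name of the score column (default `"r2_mean"`).
#' @return `n_rows x n_cols` numeric matrix.
#' @export
performance_heatmap <- function(scores, layout, value = "r2_mean") {
  if (!all(c("channel", value) %in% names(scores)))
    stop_invalid("scores must have columns 'channel' and '", value, "'")
  if (!setequal(scores$channel, layout$table$channel))
    stop_invalid("scores and layout cover different channel sets")
  m <- matrix(NA_real_, layout$n_rows, layout$n_cols,
              dimnames = list(row = paste0("*", seq_len(layout$n_rows)),
                              col = paste0("#", seq_len(layout$n_cols))))
  pos <- layout$table[match(scores$channel, layout$table$channel), ]
  m[cbind(pos$row, pos$col)] <- scores[[value]]
  m
}

#' Compare two band sets on the same dataset
#'
#' Runs the full pipeline twice — once per band set — on the same split and
#' compares held-out mean R-squared. Used to ask whether physiological band
#' edges beat a uniform fractionized partition of the same range.
#'
#' @param dataset a `synthetic_dataset`.
#' @param set_a,set_b two [band_set()]s.
#' @param config a [decoding_config()] (its `bands` field is overridden).
#' @return list with `r2_a`, `r2_b` (mean held-out R-squared) and the two
#'   full results.
#' @export
compare_band_sets <- function(dataset, set_a, set_b,
                              config = decoding_config()) {
  validate_band_set(set_a); validate_band_set(set_b)
  run_one <- function(bs) {
    cfg <- config; cfg$bands <- bs
    ctx <- prepare_decoding(dataset, cfg)
    out <- decode_full(ctx)
    rm(ctx); gc(FALSE)
    out
  }
  fa <- run_one(set_a); fb <- run_one(set_b)
  list(r2_a = fa$r2$mean, r2_b = fb$r2$mean, fit_a = fa, fit_b = fb)
}

#' End-to-end analysis of one session
#'
#' Simulates (or loads) a dataset, preprocesses it, fits the decoder with
#' cross-validated latent-count selection, runs both electrode-selection
#' procedures, the column/row group tables, the band-contribution analysis
#' and per-band decoding, and returns everything as one structured report,
#' reproducible from the stored config and seed.
#'
#' @param generator_config list for [make_dataset()]; ignored when
#'   `load_path` is given.
#' @param config a [decoding_config()].
#' @param sizes electrode-group sizes (default: [run_selection()] default).
#' @param load_path optional directory written by [write_dataset()]; when
#'   set, simulation is skipped and the dataset is read from disk.
#' @return an `analysis_report` list: `global` (per-axis + mean R-squared,
#'   n_latent), `cv_curve`, `selection`, `contributions`, `per_band`,
#'   `heatmap`, `truth`, `generator_config`, `decoding_config`, `seed`.
#' @export
run_full_analysis <- function(generator_config = list(),
                              config = decoding_config(),
                              sizes = NULL, load_path = NULL) {
  dataset <- if (is.null(load_path)) make_dataset(generator_config)
             else read_dataset(load_path)
  ctx <- prepare_decoding(dataset, config)
  curve <- cross_validate(ctx$train$X, ctx$train$Y,
                          max_latent = config$max_latent,
                          k_folds = config$k_folds)
  n_latent <- if (is.null(config$n_latent))
    select_n_latent(curve, config$plateau_tol, config$latent_cap)
  else as.integer(config$n_latent)
  global <- decode_full(ctx, n_latent)
  sel <- run_selection(ctx, sizes = sizes, n_latent = n_latent)
  contrib <- if (n_latent > 0L) band_contribution(global$model) else NULL
  perband <- per_band_decoding(ctx, n_latent = n_latent)
  heat <- performance_heatmap(sel$single_channel, ctx$train$layout)
  structure(list(
    global = list(r2 = global$r2, n_latent = n_latent),
    cv_curve = as.data.frame(curve),
    selection = sel,
    contributions = contrib,
    per_band = perband,
    heatmap = heat,
    truth = dataset$truth,
    generator_config = dataset$config,
    decoding_config = config,
    seed = dataset$seed),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  held-out R2: x=%.4f y=%.4f z=%.4f mean=%.4f (%d latent variables)\n",
              x$global$r2$per_axis[[1]], x$global$r2$per_axis[[2]],
              x$global$r2$per_axis[[3]], x$global$r2$mean, x$global$n_latent))
  if (!is.null(x$contributions)) {
    top <- x$contributions[order(-x$contributions$mean), ][1, ]
    cat(sprintf("  top contributing band: %s (%.1f%% mean contribution)\n",
                top$band, top$mean))
  } else {
    cat("  no latent variables retained (no decodable signal)\n")
  }
  cat(sprintf("  best performance-based group: %d electrode(s)\n",
              x$selection$performance$best_size))
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes the report as one JSON document plus flat CSV tables (CV curve,
#' single-channel scores, group scores, contributions, per-band R-squared,
#' heatmap matrix) under `dir`. Files are written to a temporary name and
#' renamed into place.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    global = list(r2_per_axis = as.list(report$global$r2$per_axis),
                  r2_mean = report$global$r2$mean,
                  n_latent = report$global$n_latent),
    best_performance_size = report$selection$performance$best_size,
    truth = serialize_truth(report$truth),
    seed = report$seed,
    generator_config = serializable_config(report$generator_config),
    decoding_config = serializable_config(report$decoding_config))
  atomic_write(file.path(dir, "report.json"), function(p)
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  tables <- list(cv_curve = report$cv_curve,
                 single_channel = report$selection$single_channel,
                 location_groups = report$selection$location$scores,
                 performance_groups = report$selection$performance$scores,
                 column_groups = report$selection$columns$scores,
                 row_groups = report$selection$rows$scores,
                 per_band = report$per_band)
  if (!is.null(report$contributions))
    tables$contributions <- as.data.frame(report$contributions)
  for (nm in names(tables))
    atomic_write(file.path(dir, paste0(nm, ".csv")), function(p)
      utils::write.csv(tables[[nm]], p, row.names = FALSE))
  atomic_write(file.path(dir, "heatmap.csv"), function(p)
    utils::write.csv(as.data.frame(report$heatmap), p, row.names = TRUE))
  invisible(dir)
}

serializable_config <- function(cfg) {
  lapply(cfg, function(v) {
    if (inherits(v, "band_set")) as.data.frame(v)
    else if (inherits(v, "lag_spec") || inherits(v, "ground_truth")) unclass(v)
    else v
  })
}

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
}
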