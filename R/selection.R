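#' Single-electrode decoding scores
#'
#' Fits the decoder restricted to each electrode alone (optionally to one
#' band or a band subset within that electrode) on the training segment and
#' evaluates mean R-squared on the held-out test segment. The table is
#' sorted by descending score with ties broken by ascending channel id —
#' the ranking that drives performance-based selection.
#'
#' @param dataset a `synthetic_dataset`, or a prepared `decoder_context`.
#' @param config a [decoding_config()] (ignored if a context is passed).
#' @param bands optional character vector of band names to restrict to.
#' @param n_latent latent count; defaults to the context policy.
#' @return data.frame with `channel`, `r2_x`, `r2_y`, `r2_z`, `r2_mean`,
#'   sorted descending by `r2_mean`.
#' @export
single_channel_scores <- function(dataset, config = decoding_config(),
                                  bands = NULL, n_latent = NULL) {
  ctx <- as_decoder_context(dataset, config)
  if (is.null(n_latent)) n_latent <- context_n_latent(ctx)
  channels <- sort(unique(ctx$train$index$channel))
  rows <- lapply(channels, function(ch) {
    cols <- cols_for(ctx, channels = ch, bands = bands)
    if (length(cols) == 0L) stop_invalid("no design columns for channel ", ch)
    r2 <- eval_restricted(ctx, cols, n_latent)$r2
    data.frame(channel = ch, r2_x = r2$per_axis[[1]], r2_y = r2$per_axis[[2]],
               r2_z = r2$per_axis[[3]], r2_mean = r2$mean)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$r2_mean, tab$channel), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

as_decoder_context <- function(dataset, config) {
  if (inherits(dataset, "decoder_context")) dataset else
    prepare_decoding(dataset, config)
}

#' Performance-based incremental electrode selection
#'
#' Adds electrodes in order of their single-electrode ranking and refits
#' the full decoder with the top-k set for each requested k, giving the
#' R-squared versus electrode-count curve whose argmax is the recommended
#' working set.
#'
#' @param ranking table from [single_channel_scores()] (must cover every
#'   channel).
#' @param dataset dataset or prepared `decoder_context`.
#' @param sizes ascending electrode counts to evaluate.
#' @param config a [decoding_config()].
#' @param n_latent latent count; defaults to the context policy.
#' @return a `selection_result` (method `"performance"`).
#' @export
incremental_performance <- function(ranking, dataset, sizes,
                                    config = decoding_config(),
                                    n_latent = NULL) {
  ctx <- as_decoder_context(dataset, config)
  all_ch <- sort(unique(ctx$train$index$channel))
  if (!setequal(ranking$channel, all_ch))
    stop_invalid("ranking must cover every layout channel exactly once")
  groups <- lapply(sizes, function(k) ranking$channel[seq_len(k)])
  res <- evaluate_groups(groups, ctx, config = config, n_latent = n_latent,
                         method = "performance")
  res$ranking <- ranking
  res$best_size <- sizes[which.max(res$scores$r2_mean)]
  res
}

#' Evaluate decoder performance for a list of electrode groups
#'
#' Fits and evaluates one decoder per channel group on the common
#' train/test split. Used for both selection methods and for the
#' column/row group tables.
#'
#' @param groups list (optionally named) of channel-id vectors.
#' @param dataset dataset or prepared `decoder_context`.
#' @param config a [decoding_config()].
#' @param n_latent latent count; defaults to the context policy.
#' @param method label stored on the result (`"location"`, `"performance"`,
#'   `"column"`, `"row"`, ...).
#' @return a `selection_result`: list with `method`, `groups`, and `scores`
#'   (data.frame: group, size, r2_x, r2_y, r2_z, r2_mean).
#' @export
evaluate_groups <- function(groups, dataset, config = decoding_config(),
                            n_latent = NULL, method = "location") {
  ctx <- as_decoder_context(dataset, config)
  if (length(groups) == 0L) stop_invalid("no groups to evaluate")
  if (any(lengths(groups) == 0L)) stop_invalid("empty channel group")
  if (is.null(n_latent)) n_latent <- context_n_latent(ctx)
  labels <- if (!is.null(names(groups)) && all(nzchar(names(groups))))
    names(groups) else as.character(lengths(groups))
  rows <- mapply(function(g, lab) {
    cols <- cols_for(ctx, channels = g)
    if (length(cols) == 0L) stop_invalid("group '", lab, "' matches no design columns")
    r2 <- eval_restricted(ctx, cols, n_latent)$r2
    data.frame(group = lab, size = length(g),
               r2_x = r2$per_axis[[1]], r2_y = r2$per_axis[[2]],
               r2_z = r2$per_axis[[3]], r2_mean = r2$mean,
               stringsAsFactors = FALSE)
  }, groups, labels, SIMPLIFY = FALSE)
  structure(list(method = method, groups = groups,
                 scores = do.call(rbind, rows), n_latent = n_latent),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method: %s, %d group(s)\n", x$method,
              length(x$groups)))
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Run both electrode-selection procedures
#'
#' Location-based: nested groups expanding from the central sulcus
#' ([location_groups()]). Performance-based: single-electrode ranking
#' followed by incremental top-k refits. Column and row partitions are
#' evaluated as well.
#'
#' @param dataset dataset or prepared `decoder_context`.
#' @param sizes group sizes for both methods (default: multiples of 3 up
#'   to, and always including, the full channel count).
#' @param config a [decoding_config()].
#' @param n_latent latent count; defaults to the context policy (resolved
#'   once and reused across all fits).
#' @return list with `location`, `performance`, `columns`, `rows`
#'   (selection_results) and `single_channel` (ranking table).
#' @export
run_selection <- function(dataset, sizes = NULL, config = decoding_config(),
                          n_latent = NULL) {
  ctx <- as_decoder_context(dataset, config)
  layout <- ctx$train$layout
  n_ch <- nrow(layout$table)
  if (is.null(sizes)) sizes <- unique(c(seq(3L, n_ch, by = 3L), n_ch))
  if (is.null(n_latent)) n_latent <- context_n_latent(ctx)
  loc <- evaluate_groups(location_groups(layout, sizes), ctx,
                         n_latent = n_latent, method = "location")
  ranking <- single_channel_scores(ctx, n_latent = n_latent)
  perf <- incremental_performance(ranking, ctx, sizes, n_latent = n_latent)
  cols <- evaluate_groups(column_groups(layout), ctx,
                          n_latent = n_latent, method = "column")
  rws <- evaluate_groups(row_groups(layout), ctx,
                         n_latent = n_latent, method = "row")
  list(location = loc, performance = perf, columns = cols, rows = rws,
       single_channel = ranking, n_latent = n_latent)
}
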