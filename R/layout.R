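#' Electrode grid layout
#'
#' Rectangular ECoG grid over primary motor cortex. Column 1 is the column
#' nearest the central sulcus (CS) in the rostral-caudal direction; row 1 is
#' the most medial row along the medial-lateral axis. Channel ids are
#' assigned column-major by default (column 1 holds ids 1..n_rows), but any
#' assignment can be passed via `table`.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param channel_ids integer labels, length `n_rows * n_cols`, assigned
#'   column-major (down column 1 from row 1, then column 2, ...). Ignored if
#'   `table` is given.
#' @param table optional data.frame with columns `channel`, `row`, `col` for
#'   arbitrary assignments.
#' @return an `electrode_layout` with a `$table` (channel, row, col).
#' @examples
#' monkey_b <- electrode_layout(n_rows = 8, n_cols = 4)   # 32-channel grid
#' monkey_a <- electrode_layout(n_rows = 5, n_cols = 3)   # 15-channel grid
#' @export
electrode_layout <- function(n_rows, n_cols,
                             channel_ids = seq_len(n_rows * n_cols),
                             table = NULL) {
  check_scalar_pos(n_rows, "n_rows"); check_scalar_pos(n_cols, "n_cols")
  if (is.null(table)) {
    if (length(channel_ids) != n_rows * n_cols)
      stop_invalid("channel_ids must have length n_rows * n_cols")
    table <- data.frame(channel = as.integer(channel_ids),
                        row = rep(seq_len(n_rows), times = n_cols),
                        col = rep(seq_len(n_cols), each = n_rows))
  }
  stopifnot(all(c("channel", "row", "col") %in% names(table)))
  if (anyDuplicated(table$channel)) stop_invalid("duplicate channel ids")
  if (anyDuplicated(table[, c("row", "col")])) stop_invalid("duplicate grid positions")
  if (any(table$row < 1 | table$row > n_rows | table$col < 1 | table$col > n_cols))
    stop_invalid("grid positions out of range")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 table = table[order(table$channel), , drop = FALSE]),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d x %d grid, %d channels (col 1 = CS side)\n",
              x$n_rows, x$n_cols, nrow(x$table)))
  invisible(x)
}

layout_channels <- function(layout) layout$table$channel

#' Grid position of a channel
#'
#' @param layout an [electrode_layout()].
#' @param channel a channel id present in the layout.
#' @return `c(row, col)`.
#' @export
position_of <- function(layout, channel) {
  i <- match(channel, layout$table$channel)
  if (is.na(i)) stop_invalid("unknown channel id: ", channel)
  c(row = layout$table$row[i], col = layout$table$col[i])
}

#' Location-based electrode groups expanding from the central sulcus
#'
#' Builds nested channel groups by taking whole columns in order of
#' proximity to the CS (column 1 first) and, within a column, filling from
#' the lateral end inward (highest row index first, row 1 being most
#' medial), truncated to each requested size.
#'
#' @param layout an [electrode_layout()].
#' @param sizes ascending group sizes, e.g. `c(3, 6, 9, 12, 16)`.
#' @param fill_order `"lateral_first"` (default) or `"medial_first"` within a
#'   column.
#' @return list of integer channel-id vectors, nested by construction.
#' @export
location_groups <- function(layout, sizes,
                            fill_order = c("lateral_first", "medial_first")) {
  fill_order <- match.arg(fill_order)
  n <- nrow(layout$table)
  if (is.unsorted(sizes, strictly = TRUE)) stop_invalid("sizes must be strictly ascending")
  if (max(sizes) > n) stop_invalid("requested group size exceeds channel count (", n, ")")
  tab <- layout$table
  row_key <- if (fill_order == "lateral_first") -tab$row else tab$row
  ord <- order(tab$col, row_key)
  ordered_channels <- tab$channel[ord]
  lapply(sizes, function(k) ordered_channels[seq_len(k)])
}

#' Column and row partitions of the grid
#'
#' `column_groups()` partitions channels by grid column, ordered from the CS
#' outward (column 1 first); `row_groups()` partitions by row, ordered from
#' the medial edge outward (row 1 first).
#'
#' @param layout an [electrode_layout()].
#' @return named list mapping `"#1"`/`"*1"` etc. to channel-id vectors.
#' @export
column_groups <- function(layout) {
  g <- split(layout$table$channel, layout$table$col)
  stats::setNames(g[order(as.integer(names(g)))],
                  paste0("#", sort(as.integer(names(g)))))
}

#' @rdname column_groups
#' @export
row_groups <- function(layout) {
  g <- split(layout$table$channel, layout$table$row)
  stats::setNames(g[order(as.integer(names(g)))],
                  paste0("*", sort(as.integer(names(g)))))
}
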