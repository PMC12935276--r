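#' Equal-area partition of the pitch
#'
#' Tiles the 120 x 80 event-coordinate grid into `n_rows * n_cols` equal-area
#' rectangular regions. The default 5 x 6 layout gives the standard 30
#' regions: each third of the pitch (defensive, central, attacking) split
#' into 10 cells. Coarser (3 x 5 = 15) and finer (8 x 12 = 96) layouts are
#' supported through the two arguments.
#'
#' @param n_rows number of rows (across the pitch width, from `y`).
#' @param n_cols number of columns (along the pitch length, from `x`).
#' @return a `field_partition` object.
#' @examples
#' p <- field_partition()
#' p$n_regions            # 30
#' p$cell_area            # 320 square units each
#' @export
field_partition <- function(n_rows = 5L, n_cols = 6L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1, n_cols >= 1)
  structure(list(
    n_rows = n_rows, n_cols = n_cols,
    field_length = .field_length, field_width = .field_width,
    cell_length = .field_length / n_cols,
    cell_width = .field_width / n_rows,
    cell_area = (.field_length / n_cols) * (.field_width / n_rows),
    n_regions = n_rows * n_cols
  ), class = "field_partition")
}

#' @export
print.field_partition <- function(x, ...) {
  cat("field_partition:", x$n_rows, "x", x$n_cols, "=", x$n_regions,
      "equal-area regions of", x$cell_length, "x", x$cell_width, "units\n")
  invisible(x)
}

#' Map pitch coordinates to their region
#'
#' Bins are half-open (`[k*w, (k+1)*w)`) with the final bin closed at the
#' upper pitch boundary, so every coordinate in range maps to exactly one
#' region. Indices are zero-based: rows count from `y = 0`, columns from
#' `x = 0`, and the flat index is row-major (`row * n_cols + col`), matching
#' the usual numbering of the 30-region pitch diagram.
#'
#' @param x,y coordinates (vectorized), `x` in `[0, 120]`, `y` in `[0, 80]`.
#' @param partition a [field_partition()].
#' @return data.frame with zero-based `row`, `col` and `flat` indices.
#' @examples
#' region_of(120, 80)  # bottom-right corner: row 4, col 5, flat 29
#' @export
region_of <- function(x, y, partition = field_partition()) {
  stopifnot(inherits(partition, "field_partition"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > partition$field_length))
    stop("x out of range [0, ", partition$field_length, "]")
  if (any(!is.finite(y)) || any(y < 0) || any(y > partition$field_width))
    stop("y out of range [0, ", partition$field_width, "]")
  col <- pmin(floor(x / partition$cell_length), partition$n_cols - 1L)
  row <- pmin(floor(y / partition$cell_width), partition$n_rows - 1L)
  data.frame(row = as.integer(row), col = as.integer(col),
             flat = as.integer(row * partition$n_cols + col))
}

#' Split a match into ten half-aware intervals
#'
#' Each half, including its injury time, is divided into five equal,
#' contiguous intervals; intervals 1-5 cover the first half and 6-10 the
#' second, so no interval ever mixes events from both halves. Interval
#' lengths are constant within a half but may differ between halves when the
#' halves ran for different total times.
#'
#' @param period_end_s numeric of length 2: the full duration in seconds of
#'   the first and second half (injury time included).
#' @return data.frame with one row per interval: `interval` (1-10), `period`,
#'   `start_s`, `end_s`, `dt_s`.
#' @examples
#' s <- build_interval_scheme(c(2820, 2940))
#' unique(s$dt_s)  # 564 and 588 seconds
#' @export
build_interval_scheme <- function(period_end_s) {
  if (length(period_end_s) != 2 || any(!is.finite(period_end_s)) ||
      any(period_end_s <= 0))
    stop("period_end_s must give two positive half durations (seconds)")
  dt <- rep(period_end_s / 5, each = 5)
  local <- rep(0:4, times = 2)
  start <- local * dt
  data.frame(interval = 1:10,
             period = rep(1:2, each = 5),
             start_s = start,
             end_s = start + dt,
             dt_s = dt)
}

#' Locate events within the interval scheme
#'
#' Assigns each event to the interval containing its start time. Bins are
#' half-open with the final interval of each half closed at the half's end,
#' so an event stamped exactly at the period end falls into interval 5 (or
#' 10), never out of range.
#'
#' @param time_s event start times, seconds from the start of their period.
#' @param period 1 or 2, vectorized with `time_s`.
#' @param scheme a scheme from [build_interval_scheme()].
#' @return integer interval indices in 1-10.
#' @export
interval_of <- function(time_s, period, scheme) {
  dt <- ifelse(period == 1, scheme$dt_s[1], scheme$dt_s[6])
  end <- ifelse(period == 1, scheme$end_s[5], scheme$end_s[10])
  if (any(time_s < 0 | time_s > end))
    stop("time_s outside its period's [0, end] range")
  local <- pmin(floor(time_s / dt), 4)
  as.integer(local + 1L + (period - 1L) * 5L)
}
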