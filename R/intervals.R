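#' Build a probability interval grid
#'
#' Partitions a probability range into ordered, disjoint, half-open intervals
#' `(s1, s2]`. Equal-width grids are the common case (e.g. ten deciles of
#' `(0, 1]`); explicit edge vectors allow uneven grids such as finer bins in
#' a low-probability range where predictions concentrate.
#'
#' The lowest interval absorbs its left edge, so a score exactly equal to
#' `lo` (typically 0) is binned rather than dropped.
#'
#' @param n_intervals number of equal-width intervals (ignored when `edges`
#'   is given).
#' @param lo,hi range covered, `0 <= lo < hi <= 1`.
#' @param edges optional strictly increasing numeric vector of interval
#'   edges in `[0, 1]`; overrides `n_intervals`/`lo`/`hi`.
#' @return An `interval_grid`: list with `edges` and derived `lower`/`upper`
#'   vectors.
#' @examples
#' interval_grid(10)                      # deciles of (0, 1]
#' interval_grid(edges = c(0, .05, .1, .2, .4, 1))
#' @export
interval_grid <- function(n_intervals = 10, lo = 0, hi = 1, edges = NULL) {
  if (is.null(edges)) {
    stopifnot(length(n_intervals) == 1, n_intervals >= 1)
    if (!(lo >= 0 && lo < hi && hi <= 1)) {
      stop("require 0 <= lo < hi <= 1, got lo=", lo, ", hi=", hi)
    }
    edges <- seq(lo, hi, length.out = n_intervals + 1)
  }
  edges <- as.numeric(edges)
  if (length(edges) < 2) stop("need at least two edges")
  if (any(diff(edges) <= 0)) stop("interval edges must be strictly increasing")
  if (edges[1] < 0 || edges[length(edges)] > 1) {
    stop("interval edges must lie within [0, 1]")
  }
  structure(list(edges = edges,
                 lower = edges[-length(edges)],
                 upper = edges[-1]),
            class = "interval_grid")
}

#' Build a quantile (equal-occupancy) interval grid
#'
#' Discretizes a set of scores into quantile bins: edges are placed at the
#' empirical quantiles so every interval holds (up to ties) the same number
#' of points. This adapts granularity to wherever the score distribution
#' concentrates, guarantees every interval can supply the shared sample
#' count `m` without replacement, and is the discretization of choice when
#' scores pile up near one end of `[0, 1]`. The outer edges are widened to
#' `lo`/`hi` so no score is out of span.
#'
#' @param scores numeric vector of probabilities to bin.
#' @param n_intervals target number of intervals (fewer if heavy ties).
#' @param lo,hi outer span of the grid.
#' @return An `interval_grid`.
#' @export
quantile_grid <- function(scores, n_intervals = 10, lo = 0, hi = 1) {
  if (length(scores) < n_intervals) {
    stop("fewer scores than requested intervals")
  }
  edges <- unique(as.numeric(
    stats::quantile(scores, seq(0, 1, length.out = n_intervals + 1))))
  edges[1] <- min(edges[1], lo)
  edges[length(edges)] <- max(edges[length(edges)], hi)
  if (length(edges) < 3) {
    stop("scores too heavily tied to form a quantile grid")
  }
  interval_grid(edges = edges)
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("<interval_grid: %d intervals spanning (%g, %g]>\n",
              n_intervals(x), x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

n_intervals <- function(grid) length(grid$lower)

interval_labels <- function(grid) {
  sprintf("(%g,%g]", grid$lower, grid$upper)
}

#' Assign score-table points to probability intervals
#'
#' Bins each point by its score with the half-open rule `s in (s1, s2]`
#' (right edge inclusive; the grid's lowest edge is absorbed into the first
#' interval). Points whose scores fall outside the grid's span are reported
#' separately, never silently dropped.
#'
#' @param table a `score_table` with a `score` column.
#' @param grid an [interval_grid()].
#' @return An `interval_assignment`: list with `index_sets` (list of integer
#'   row indices per interval), `out_of_span` (row indices outside the grid),
#'   `occupancy` (integer vector), and the `grid`.
#' @export
assign_intervals <- function(table, grid) {
  validate_score_table(table)
  if (is.null(table$score)) stop("table has no `score` column to bin")
  s <- table$score
  lo <- grid$edges[1]
  hi <- grid$edges[length(grid$edges)]
  # findInterval on left-open bins: use negative trick via cut()
  bin <- cut(s, breaks = grid$edges, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  out <- which(s < lo | s > hi)
  bin[out] <- NA
  index_sets <- lapply(seq_len(n_intervals(grid)),
                       function(i) which(!is.na(bin) & bin == i))
  structure(list(index_sets = index_sets,
                 out_of_span = out,
                 occupancy = lengths(index_sets),
                 grid = grid),
            class = "interval_assignment")
}

#' Resolve the per-interval sample count m
#'
#' With `m = "auto"` the shared sample size is the minimum occupancy across
#' non-empty intervals, so every interval is sampled equally and without
#' replacement. An explicit `m` is returned unchanged. A warning is emitted
#' when the resolved `m` falls below 50% of any non-empty interval's
#' occupancy, since sampling too small a fraction of an interval can flip the
#' sign of small discrepancies even though their absolute value is stable.
#'
#' @param assignment an [assign_intervals()] result.
#' @param config a [sudo_config()] (its `m` is either `"auto"` or a count).
#' @return integer `m >= 2`.
#' @export
resolve_sample_size <- function(assignment, config) {
  occ <- assignment$occupancy
  nonempty <- occ[occ > 0]
  if (length(nonempty) == 0) stop("all intervals are empty")
  m <- if (identical(config$m, "auto")) min(nonempty) else as.integer(config$m)
  if (m < 2) {
    stop("resolved sample size m = ", m,
         " (< 2): cannot form a probe training task")
  }
  under <- which(occ > 0 & m < 0.5 * occ)
  if (length(under)) {
    warning("sample size m = ", m, " is below 50% of occupancy in interval(s) ",
            paste(interval_labels(assignment$grid)[under], collapse = ", "),
            "; the sign of small discrepancies may be unstable", call. = FALSE)
  }
  m
}

#' Sample m points from one interval, without replacement
#'
#' Deterministic given the seed; the same subset is reused for every
#' pseudo-label within a replicate so that performance differences are
#' attributable to the pseudo-labels, not the sample.
#'
#' @param assignment an [assign_intervals()] result.
#' @param interval_index which interval to sample from.
#' @param m sample count.
#' @param seed integer seed for this draw.
#' @return integer row indices into the original table.
#' @export
sample_interval_points <- function(assignment, interval_index, m, seed) {
  idx <- assignment$index_sets[[interval_index]]
  if (length(idx) < m) {
    stop("interval ", interval_labels(assignment$grid)[interval_index],
         " holds ", length(idx), " points; cannot sample m = ", m)
  }
  withr::with_seed(seed, idx[sample.int(length(idx), m)])
}
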