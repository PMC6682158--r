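#' Bin motion events into an activity series
#'
#' Counts motion events in consecutive half-open time bins
#' `[t_start + i*w, t_start + (i+1)*w)`. Events outside `[t_start, t_end)` are
#' excluded. Activity is reported in arbitrary units (event counts per bin, or
#' weighted sums thereof after [combine_series()]).
#'
#' @param log A `motion_log` tibble (see [parse_motion_log()]), or any data
#'   frame with an `offset_s` column.
#' @param bin_width_s Bin width in seconds (> 0; default 60).
#' @param t_start,t_end Analysis window in seconds after experiment start.
#'   Defaults: 0 and the last event time rounded up to a whole bin.
#'
#' @return An `activity_series` tibble with columns `time_s` (bin left edge,
#'   seconds) and `count`, and attribute `bin_width_s`.
#' @examples
#' log <- motion_log("2018-01-01 00:00:00", c(5, 15, 25))
#' bin_events(log, bin_width_s = 10, t_start = 0, t_end = 30)$count
#' @export
bin_events <- function(log, bin_width_s = 60, t_start = NULL, t_end = NULL) {
  check_columns(log, "offset_s", "log")
  if (!is.numeric(bin_width_s) || bin_width_s <= 0) {
    abort("`bin_width_s` must be positive.")
  }
  t_start <- t_start %||% 0
  t_end <- t_end %||% if (nrow(log)) {
    t_start + ceiling((max(log$offset_s) - t_start + 1e-9) / bin_width_s) * bin_width_s
  } else {
    t_start + bin_width_s
  }
  if (t_start >= t_end) abort("`t_start` must be < `t_end`.")
  n_bins <- ceiling((t_end - t_start) / bin_width_s - 1e-9)
  edges <- t_start + bin_width_s * (0:n_bins)
  ev <- log$offset_s[log$offset_s >= t_start & log$offset_s < t_end]
  idx <- pmin(floor((ev - t_start) / bin_width_s), n_bins - 1) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  new_activity_series(edges[-length(edges)], as.double(counts), bin_width_s)
}

new_activity_series <- function(time_s, count, bin_width_s) {
  out <- tibble(time_s = time_s, count = count)
  attr(out, "bin_width_s") <- bin_width_s
  class(out) <- c("activity_series", class(out))
  out
}

same_grid <- function(a, b) {
  isTRUE(all.equal(attr(a, "bin_width_s"), attr(b, "bin_width_s"))) &&
    nrow(a) == nrow(b) &&
    isTRUE(all.equal(a$time_s, b$time_s))
}

#' Combine activity series from several sensors
#'
#' Sums per-bin activity across sensors on an identical bin grid, each sensor
#' weighted equally by default (weighted-equally-and-summed combination of the
#' nest-box atrium and cage-top PIR sensors).
#'
#' @param series_list List of `activity_series` on the same bin grid.
#' @param weights Numeric weights, one per series (default all 1).
#' @return An `activity_series` with `count = sum_k weights[k] * count_k`.
#' @examples
#' log <- motion_log("2018-01-01 00:00:00", c(5, 15, 25))
#' s <- bin_events(log, 10, 0, 30)
#' combine_series(list(s, s))$count # doubled
#' @export
combine_series <- function(series_list, weights = NULL) {
  if (!is.list(series_list) || !length(series_list)) {
    abort("`series_list` must be a non-empty list of activity series.")
  }
  weights <- weights %||% rep(1, length(series_list))
  if (length(weights) != length(series_list)) {
    abort("`weights` must have one entry per series.")
  }
  ref <- series_list[[1]]
  check_columns(ref, c("time_s", "count"), "series_list[[1]]")
  for (k in seq_along(series_list)[-1]) {
    if (!same_grid(ref, series_list[[k]])) {
      abort(sprintf("Series %d is not on the same bin grid as series 1.", k))
    }
  }
  counts <- Reduce(`+`, Map(function(s, w) w * s$count, series_list, weights))
  new_activity_series(ref$time_s, counts, attr(ref, "bin_width_s"))
}

#' Integrate an activity series over time
#'
#' Running cumulative sum of per-bin activity; with `normalize = TRUE` the
#' curve is divided by its final value so it ends at 1 (an all-zero series
#' stays all zero). Cumulative activity curves are the basis of the
#' per-24-hour comparison against a reference sensor.
#'
#' @param series An `activity_series`.
#' @param normalize Divide by the final cumulative value? (default `TRUE`)
#' @return The series with an added `cumulative` column.
#' @examples
#' log <- motion_log("2018-01-01 00:00:00", c(5, 15, 25, 35))
#' integrate_activity(bin_events(log, 10, 0, 40))$cumulative
#' @export
integrate_activity <- function(series, normalize = TRUE) {
  check_columns(series, "count", "series")
  if (!nrow(series)) abort("`series` must be non-empty.")
  cum <- cumsum(series$count)
  if (normalize) {
    total <- cum[length(cum)]
    if (total > 0) cum <- cum / total
  }
  series$cumulative <- cum
  series
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with the preconditions used throughout the
#' activity comparison: at least three paired values and no constant input.
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 3) abort("Need at least 3 paired values.")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("Correlation undefined for constant input.")
  }
  stats::cor(a, b)
}

#' Compare activity against a reference sensor, period by period
#'
#' For each period (typically 24 h starting at dark onset), both signals are
#' binned on a common grid, cumulatively integrated and normalized, and the
#' two curves are correlated with [pearson_r()]. The mean of the per-period
#' correlations summarises agreement between sensing methods. `method =
#' "counts"` instead correlates the raw binned counts, which is the
#' appropriate scale when asking whether two signals share event-level
#' structure rather than daily shape.
#'
#' @param test,reference Each either a `motion_log` or an `activity_series`
#'   covering every requested period. Series inputs must share the requested
#'   bin grid.
#' @param period_starts Numeric vector of period start times (seconds after
#'   experiment start).
#' @param period_s Period length in seconds (default 86400, one day).
#' @param bin_width_s Common bin width in seconds (default 60).
#' @param method `"integrated"` (default: correlate normalized cumulative
#'   curves) or `"counts"` (correlate raw binned counts).
#' @return An `activity_comparison` tibble with one row per period
#'   (`period_start_s`, `r`) and attribute `mean_r`.
#' @export
compare_to_reference <- function(test, reference, period_starts,
                                 period_s = 86400, bin_width_s = 60,
                                 method = c("integrated", "counts")) {
  method <- match.arg(method)
  per_period_values <- function(x, start) {
    if (inherits(x, "motion_log")) {
      s <- bin_events(x, bin_width_s, t_start = start, t_end = start + period_s)
    } else {
      check_columns(x, c("time_s", "count"), "series")
      keep <- x$time_s >= start & x$time_s < start + period_s
      if (!any(keep)) abort(sprintf("Series does not cover period starting %g s.", start))
      s <- new_activity_series(x$time_s[keep], x$count[keep], attr(x, "bin_width_s"))
    }
    if (method == "integrated") integrate_activity(s, normalize = TRUE)$cumulative
    else s$count
  }
  r <- vapply(period_starts, function(start) {
    pearson_r(per_period_values(test, start), per_period_values(reference, start))
  }, numeric(1))
  out <- tibble(period_start_s = as.double(period_starts), r = r)
  attr(out, "mean_r") <- mean(r)
  attr(out, "method") <- method
  class(out) <- c("activity_comparison", class(out))
  out
}

#' @export
print.activity_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf("# mean r over %d period(s): %.4f (%s curves)\n",
              nrow(x), attr(x, "mean_r"), attr(x, "method")))
  invisible(x)
}
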