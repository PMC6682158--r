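#' Build an actogram from a motion log
#'
#' Folds a multi-day motion log into stacked period-long rows of binned
#' activity (one row per day at the default 86,400-s period), the standard
#' visualization of circadian activity patterns. Only complete periods are
#' kept; a partial trailing period is dropped.
#'
#' @param log A `motion_log`.
#' @param period_s Repeat period in seconds (default 86400).
#' @param bin_width_s Bin width in seconds (default 60; must not exceed
#'   `period_s`).
#' @param light_cycle Optional light schedule: a data frame with columns
#'   `on_s`, `off_s` giving light-phase start/end offsets within a period
#'   (e.g. 16 h light starting at t = 0: `tibble(on_s = 0, off_s = 16*3600)`).
#' @param t_start Fold origin in seconds after experiment start (default 0);
#'   set this to dark-cycle onset to align rows with the dark phase.
#' @param t_end End of the recording in seconds (default: time of the last
#'   event). Supply this when the recording ran beyond the last event so that
#'   trailing quiet periods still count as complete.
#'
#' @return An `actogram` tibble with columns `period` (1-based row index),
#'   `time_s` (bin left edge within the period) and `count`; attributes
#'   `period_s`, `bin_width_s`, `light_cycle`.
#' @examples
#' log <- gen_motion_events(physiology_profile(duration_s = 2 * 86400), seed = 1)
#' act <- build_actogram(log)
#' dplyr::count(act, period)
#' @export
build_actogram <- function(log, period_s = 86400, bin_width_s = 60,
                           light_cycle = NULL, t_start = 0, t_end = NULL) {
  check_columns(log, "offset_s", "log")
  if (period_s < bin_width_s) abort("`period_s` must be >= `bin_width_s`.")
  t_end <- t_end %||% if (nrow(log)) max(log$offset_s) else t_start
  n_periods <- floor((t_end - t_start) / period_s)
  if (n_periods < 1) abort("Log must span at least one full period.")
  rows <- lapply(seq_len(n_periods), function(p) {
    s0 <- t_start + (p - 1) * period_s
    s <- bin_events(log, bin_width_s, t_start = s0, t_end = s0 + period_s)
    tibble(period = p, time_s = s$time_s - s0, count = s$count)
  })
  out <- bind_rows(rows)
  attr(out, "period_s") <- period_s
  attr(out, "bin_width_s") <- bin_width_s
  attr(out, "light_cycle") <- light_cycle
  class(out) <- c("actogram", class(out))
  out
}

#' Plot an actogram
#'
#' One panel per period (day), activity as vertical bars, with the light phase
#' shaded white and the dark phase grey when a light cycle is attached.
#'
#' @param object An `actogram` from [build_actogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.actogram <- function(object, ...) {
  lc <- attr(object, "light_cycle")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 3600, y = .data$count))
  if (!is.null(lc)) {
    period_h <- attr(object, "period_s") / 3600
    dark <- dark_phases(lc, attr(object, "period_s"))
    p <- p + ggplot2::geom_rect(
      data = dark, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$from_s / 3600, xmax = .data$to_s / 3600,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80"
    ) + ggplot2::coord_cartesian(xlim = c(0, period_h), expand = FALSE)
  }
  p +
    ggplot2::geom_col(width = attr(object, "bin_width_s") / 3600, fill = "black") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$period)) +
    ggplot2::labs(x = "Time in period (h)", y = "Activity (a.u.)")
}

# complement of the light phases within one period
dark_phases <- function(light_cycle, period_s) {
  on <- sort(light_cycle$on_s)
  off <- light_cycle$off_s[order(light_cycle$on_s)]
  edges <- c(0, rbind(on, off), period_s)
  froms <- edges[seq(1, length(edges) - 1, by = 2)]
  tos <- edges[seq(2, length(edges), by = 2)]
  keep <- tos > froms
  tibble(from_s = froms[keep], to_s = tos[keep])
}
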