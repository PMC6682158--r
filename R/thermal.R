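#' Mean of the brightest fraction of thermal pixels
#'
#' Averages the `k = round(fraction * 4800)` largest raw pixel values of a
#' frame (480 pixels at the default 10%). Because a nested animal typically
#' occupies only part of the 60 x 80 field of view, with the remainder filled
#' by cooler bedding and background, restricting the average to the brightest
#' decile makes the surface-temperature estimate robust to how much of the
#' frame the animal fills. Ties at the cutoff are broken by value only: any
#' subset of tied values yields the same mean.
#'
#' @param frame A `thermal_frame`.
#' @param fraction Fraction of pixels to average, in `(0, 1]` (default 0.10).
#' @param mask_extremes Drop dead (0) and saturated (16383) pixels before
#'   ranking? Useful when lens condensation produces stuck pixels. Default
#'   `FALSE`.
#' @return Mean of the top-`k` raw pixel values (double).
#' @examples
#' f <- thermal_frame(0, matrix(c(rep(9000, 480), rep(1000, 4320)), 60, 80))
#' top_fraction_mean(f, 0.10) # 9000
#' @export
top_fraction_mean <- function(frame, fraction = 0.10, mask_extremes = FALSE) {
  stopifnot(inherits(frame, "thermal_frame"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  px <- as.double(frame$pixels)
  if (mask_extremes) px <- px[px > 0 & px < LEPTON_MAX]
  if (!length(px)) abort("No pixels left after masking extremes.")
  k <- max(1L, round(fraction * length(px)))
  mean(sort(px, decreasing = TRUE, method = "quick")[seq_len(k)])
}

#' Fit a linear raw-unit-to-temperature calibration
#'
#' Ordinary least-squares fit of reference temperature (response) on raw
#' camera units (predictor): `temp_c = slope * raw + intercept`. Calibration
#' pairs are collected by imaging a surface of known temperature (e.g. a
#' thermal-cycler block) at several set points. The calibration is per camera
#' instance; no emissivity or ambient compensation is applied.
#'
#' @param pairs Data frame with columns `raw` (raw units) and `temp_c`
#'   (reference temperature, Celsius); alternatively supply the two vectors.
#' @param raw,temp_c Numeric vectors (alternative interface).
#' @return A `thermal_calibration` object: list with `slope` (deg C per raw
#'   unit), `intercept` (deg C), `r_squared`, `n_points`, and standard errors.
#'   Supports [tidy()] and [glance()].
#' @examples
#' cal <- fit_calibration(tibble::tibble(raw = c(7000, 7500, 8000),
#'                                       temp_c = c(20, 25, 30)))
#' cal$slope
#' @export
fit_calibration <- function(pairs = NULL, raw = NULL, temp_c = NULL) {
  if (!is.null(pairs)) {
    check_columns(pairs, c("raw", "temp_c"), "pairs")
    raw <- pairs$raw
    temp_c <- pairs$temp_c
  }
  if (length(raw) != length(temp_c)) abort("`raw` and `temp_c` must have equal length.")
  if (length(raw) < 2) abort("Degenerate fit: need at least 2 calibration pairs.")
  if (length(unique(raw)) < 2) {
    abort("Degenerate fit: all raw values identical.")
  }
  fit <- lm(temp_c ~ raw, data = data.frame(raw = raw, temp_c = temp_c))
  sm <- suppressWarnings(summary(fit)) # exact lines warn about perfect fits
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    n_points = length(raw),
    slope_se = sm$coefficients["raw", "Std. Error"],
    intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
    sigma = sm$sigma
  ), class = "thermal_calibration")
}

#' @export
print.thermal_calibration <- function(x, ...) {
  cat(sprintf("<thermal_calibration> temp_c = %.6g * raw + %.6g  (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `thermal_calibration`.
#' @param ... Unused.
#' @export
tidy.thermal_calibration <- function(x, ...) {
  tibble(term = c("(Intercept)", "raw"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se))
}

#' @rdname fit_calibration
#' @export
glance.thermal_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma, nobs = x$n_points)
}

#' Persist / load a calibration as JSON
#'
#' @param cal A `thermal_calibration`.
#' @param path JSON file path.
#' @return [read_calibration_json()] returns a `thermal_calibration`.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "thermal_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "thermal_calibration")
}

#' Convert thermal frames to a surface-temperature series
#'
#' Applies [top_fraction_mean()] to each frame and maps the raw-unit mean to
#' Celsius through a linear calibration:
#' `temp_c = slope * top_fraction_mean + intercept`.
#'
#' @param frames List of `thermal_frame`s, ordered by `time_s`.
#' @param calibration A `thermal_calibration`.
#' @param fraction Top-pixel fraction (default 0.10).
#' @param mask_extremes Passed to [top_fraction_mean()].
#' @return A `temperature_series` tibble with columns `time_s`, `temp_c` and
#'   attribute `fraction_used`.
#' @export
frames_to_temperature <- function(frames, calibration, fraction = 0.10,
                                  mask_extremes = FALSE) {
  if (!is.list(frames) || !length(frames)) abort("`frames` must be a non-empty list.")
  stopifnot(inherits(calibration, "thermal_calibration"))
  times <- vapply(frames, `[[`, numeric(1), "time_s")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("Frames must be strictly ordered in time.")
  }
  raw_means <- vapply(frames, top_fraction_mean, numeric(1),
                      fraction = fraction, mask_extremes = mask_extremes)
  out <- tibble(time_s = times,
                temp_c = calibration$slope * raw_means + calibration$intercept)
  attr(out, "fraction_used") <- fraction
  class(out) <- c("temperature_series", class(out))
  out
}

#' Mean absolute deviation between paired temperature measurements
#'
#' The validation statistic comparing the thermal-camera readout against a
#' contact thermistor: the arithmetic mean of absolute pairwise differences.
#' Precomputed per-condition deviations (as printed in a validation table) can
#' be supplied directly via `deviations`.
#'
#' @param a,b Equal-length paired measurements in Celsius.
#' @param deviations Alternatively, precomputed per-condition absolute
#'   deviations to average.
#' @return Mean absolute deviation in Celsius.
#' @examples
#' mean_abs_deviation(deviations = c(0.45, 1.63, 0.64, 0.28, 0.35, 0.58, 1.26))
#' @export
mean_abs_deviation <- function(a = NULL, b = NULL, deviations = NULL) {
  if (!is.null(deviations)) {
    if (any(deviations < 0)) abort("`deviations` must be non-negative.")
    return(mean(deviations))
  }
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (!length(a)) abort("Need at least one pair.")
  mean(abs(a - b))
}

#' Plot a surface-temperature series
#'
#' @param object A `temperature_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.temperature_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$temp_c)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Surface temperature (°C)")
}
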