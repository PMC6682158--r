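#' Time-series CSV files
#'
#' All scalar time series produced by the analysis (activity counts,
#' temperatures, breathing rates) are exchanged as two-column CSV files with
#' header `time_s,value`. Values are written with 6 significant digits, which
#' bounds the round-trip error documented for these files.
#'
#' @param series A data frame with columns `time_s` and `value` (extra columns
#'   are dropped with a warning), or two vectors via `times` / `values`.
#' @param times,values Equal-length numeric vectors (alternative interface).
#' @param path Output / input CSV path.
#'
#' @return [read_series_csv()] returns a tibble with columns `time_s`, `value`;
#'   [write_series_csv()] returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_series_csv(tibble::tibble(time_s = 0:1, value = c(20.5, 21)), p)
#' read_series_csv(p)
#' @name series_csv
NULL

#' @rdname series_csv
#' @export
write_series_csv <- function(series = NULL, path, times = NULL, values = NULL) {
  if (is.null(series)) {
    if (length(times) != length(values)) {
      abort("`times` and `values` must have equal length.")
    }
    series <- tibble(time_s = as.double(times), value = as.double(values))
  }
  check_columns(series, c("time_s", "value"), "series")
  lines <- c("time_s,value",
             if (nrow(series)) {
               paste(signif(series$time_s, 10), signif(series$value, 6), sep = ",")
             })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  check_columns(df, c("time_s", "value"), "CSV file")
  as_tibble(df[c("time_s", "value")])
}
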