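#' Motion event logs
#'
#' A motion event log records, for one passive-infrared (PIR) sensor, the time
#' of every motion event it observed. On disk it is a plain-text file
#' (`motion.txt` dialect): a header comment
#' `# start: YYYY-MM-DD HH:MM:SS` giving the experiment start time, followed by
#' one full timestamp per line, in the same format, for each sensor activation.
#' Fractional seconds are accepted via an optional `.fff` suffix.
#'
#' In memory the log is a tibble with one row per event:
#' \describe{
#'   \item{timestamp}{`POSIXct` event time (timezone-naive, parsed as UTC).}
#'   \item{offset_s}{seconds after the experiment start (non-negative double).}
#' }
#' The experiment start time is stored in the `start_time` attribute. Events
#' must be non-decreasing in time; an empty log (header only) is valid.
#'
#' @param lines Character vector of raw lines (header first), as read from a
#'   `motion.txt` file.
#' @param path Path to a motion log file.
#' @param log A `motion_log` tibble as returned by [parse_motion_log()].
#' @param start_time `POSIXct` experiment start.
#' @param offsets_s Numeric vector of event offsets (seconds after start),
#'   non-decreasing and non-negative.
#'
#' @return `parse_motion_log()` and `read_motion_log()` return a `motion_log`
#'   tibble; `write_motion_log()` returns `path` invisibly;
#'   `motion_log()` constructs a log from components.
#' @examples
#' log <- parse_motion_log(c(
#'   "# start: 2018-01-01 00:00:00",
#'   "2018-01-01 00:01:30"
#' ))
#' log$offset_s # 90
#' @name motion_log
NULL

.ts_format <- "%Y-%m-%d %H:%M:%OS"

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, format = .ts_format, tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort(sprintf("Unparseable timestamp: '%s' (expected YYYY-MM-DD HH:MM:SS[.fff]).",
                  x[which(bad)[1]]))
  }
  out
}

format_timestamp <- function(t) {
  sub <- as.numeric(t) %% 1
  if (any(sub > 1e-9)) format(t, "%Y-%m-%d %H:%M:%OS3", tz = "UTC")
  else format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")
}

new_motion_log <- function(timestamp, offset_s, start_time) {
  out <- tibble(timestamp = timestamp, offset_s = as.double(offset_s))
  attr(out, "start_time") <- start_time
  class(out) <- c("motion_log", class(out))
  out
}

#' @rdname motion_log
#' @export
motion_log <- function(start_time, offsets_s = numeric()) {
  if (!inherits(start_time, "POSIXct")) start_time <- parse_timestamp(start_time)
  offsets_s <- as.double(offsets_s)
  if (any(offsets_s < 0)) abort("Event offsets must be >= 0.")
  if (is.unsorted(offsets_s)) abort("Event offsets must be non-decreasing.")
  new_motion_log(start_time + offsets_s, offsets_s, start_time)
}

#' @rdname motion_log
#' @export
parse_motion_log <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("Empty motion log: missing '# start:' header.")
  header <- lines[[1]]
  m <- regmatches(header, regexec("^#\\s*start:\\s*(.+)$", header))[[1]]
  if (length(m) < 2) {
    abort(sprintf("Motion log must begin with '# start: <timestamp>' header; got '%s'.",
                  header))
  }
  start_time <- parse_timestamp(m[[2]])
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  if (!length(body)) return(new_motion_log(start_time[0], double(), start_time))
  ts <- parse_timestamp(body)
  offsets <- as.double(difftime(ts, start_time, units = "secs"))
  if (any(offsets < 0)) {
    i <- which(offsets < 0)[1]
    abort(sprintf("Event on line %d ('%s') precedes the experiment start.",
                  i + 1L, body[i]))
  }
  if (is.unsorted(offsets)) {
    i <- which(diff(offsets) < 0)[1] + 1L
    abort(sprintf("Events are not in non-decreasing order at line %d ('%s').",
                  i + 1L, body[i]))
  }
  new_motion_log(ts, offsets, start_time)
}

#' @rdname motion_log
#' @export
read_motion_log <- function(path) {
  parse_motion_log(readLines(path, warn = FALSE))
}

#' @rdname motion_log
#' @export
write_motion_log <- function(log, path) {
  check_columns(log, c("timestamp", "offset_s"), "log")
  start <- attr(log, "start_time")
  if (is.null(start)) abort("`log` lacks a start_time attribute.")
  lines <- c(paste0("# start: ", format_timestamp(start)),
             if (nrow(log)) format_timestamp(log$timestamp))
  writeLines(lines, path)
  invisible(path)
}
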