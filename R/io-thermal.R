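#' Thermal frames
#'
#' The long-wave infrared imager writes one delimited text file per time step:
#' a 60-row by 80-column matrix (4,800 pixels) of raw camera counts ("Lepton
#' units", 14-bit, 0--16383). The acquisition time of a frame is encoded in its
#' file name: the last contiguous run of digits before the extension is the
#' time in seconds after experiment start (e.g. `therm_000123.txt` is t = 123 s).
#' Both comma- and whitespace-delimited matrices are accepted.
#'
#' A `thermal_frame` is a list with elements `time_s` (seconds after start) and
#' `pixels` (a 60 x 80 integer matrix).
#'
#' @param lines Character vector holding the 60 matrix rows.
#' @param filename File name (or path) carrying the time token.
#' @param path Path to a frame file, or for [read_thermal_dir()] a directory of
#'   frame files.
#' @param frame A `thermal_frame`.
#' @param time_s Seconds after experiment start.
#' @param pixels 60 x 80 numeric matrix of raw units.
#' @param pattern Regular expression selecting frame files within the directory.
#'
#' @return A `thermal_frame`, or for [read_thermal_dir()] a list of frames
#'   sorted by `time_s`.
#' @examples
#' f <- thermal_frame(5, matrix(8000L, 60, 80))
#' top_fraction_mean(f, 0.10)
#' @name thermal_frame
NULL

LEPTON_ROWS <- 60L
LEPTON_COLS <- 80L
LEPTON_MAX <- 16383L

#' @rdname thermal_frame
#' @export
thermal_frame <- function(time_s, pixels) {
  pixels <- as.matrix(pixels)
  if (!identical(dim(pixels), c(LEPTON_ROWS, LEPTON_COLS))) {
    abort(sprintf("Thermal frame must be %d x %d; got %d x %d.",
                  LEPTON_ROWS, LEPTON_COLS, nrow(pixels), ncol(pixels)))
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > LEPTON_MAX)) {
    abort(sprintf("Pixel values must lie in [0, %d].", LEPTON_MAX))
  }
  structure(list(time_s = as.double(time_s),
                 pixels = matrix(as.integer(round(pixels)),
                                 LEPTON_ROWS, LEPTON_COLS)),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> t = %g s, %d x %d raw units in [%d, %d]\n",
              x$time_s, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# last contiguous digit run before the extension -> integer seconds
frame_time_from_name <- function(filename) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(filename))
  runs <- regmatches(base, gregexpr("[0-9]+", base))[[1]]
  if (!length(runs)) {
    abort(sprintf("File name '%s' carries no digit run to use as a time token.",
                  basename(filename)))
  }
  as.double(runs[[length(runs)]])
}

#' @rdname thermal_frame
#' @export
parse_thermal_frame <- function(lines, filename) {
  time_s <- frame_time_from_name(filename)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != LEPTON_ROWS) {
    abort(sprintf("Expected %d rows in '%s'; got %d.",
                  LEPTON_ROWS, basename(filename), length(lines)))
  }
  rows <- strsplit(trimws(lines), "[,\\s]+", perl = TRUE)
  ncols <- lengths(rows)
  if (any(ncols != LEPTON_COLS)) {
    bad <- which(ncols != LEPTON_COLS)[1]
    abort(sprintf("Row %d of '%s' has %d values; expected %d.",
                  bad, basename(filename), ncols[bad], LEPTON_COLS))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) abort(sprintf("Non-numeric value in '%s'.", basename(filename)))
  thermal_frame(time_s, matrix(vals, LEPTON_ROWS, LEPTON_COLS, byrow = TRUE))
}

#' @rdname thermal_frame
#' @export
read_thermal_frame <- function(path) {
  parse_thermal_frame(readLines(path, warn = FALSE), path)
}

#' @rdname thermal_frame
#' @export
write_thermal_frame <- function(frame, path) {
  stopifnot(inherits(frame, "thermal_frame"))
  writeLines(apply(frame$pixels, 1, paste, collapse = ","), path)
  invisible(path)
}

#' @rdname thermal_frame
#' @export
read_thermal_dir <- function(path, pattern = "\\.(txt|csv)$") {
  files <- list.files(path, pattern = pattern, full.names = TRUE)
  if (!length(files)) abort(sprintf("No thermal frame files found in '%s'.", path))
  frames <- lapply(files, read_thermal_frame)
  frames[order(vapply(frames, `[[`, numeric(1), "time_s"))]
}
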