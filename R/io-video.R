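#' Video frame stacks
#'
#' Near-infrared video is handled as a `frame_stack`: an ordered list of RGB
#' frames plus the frame rate and the time of the first frame. Each frame is a
#' `height x width x 3` integer array with 8-bit channel values (0--255).
#'
#' On disk a stack is a lossless PNG frame-sequence directory: numbered
#' `frame_000001.png` files plus a `frames.json` metadata file recording `fps`
#' and `t0`. [read_video()] decodes such a directory (optionally restricted to
#' a half-open time interval); [write_video()] encodes one.
#'
#' @param frames List of `h x w x 3` arrays, values 0--255.
#' @param fps Frames per second (> 0).
#' @param t0 Time of the first frame, seconds (default 0).
#' @param path Directory holding (or to hold) the frame sequence.
#' @param start_s,end_s Half-open time window `[start_s, end_s)` to read;
#'   defaults cover the whole recording.
#' @param x,i A `frame_stack` and frame index.
#'
#' @return [frame_stack()] and [read_video()] return a `frame_stack`;
#'   [write_video()] returns `path` invisibly. `frame_times()` returns the
#'   per-frame time stamps in seconds.
#' @name frame_stack
NULL

#' @rdname frame_stack
#' @export
frame_stack <- function(frames, fps, t0 = 0) {
  if (!is.list(frames) || !length(frames)) abort("`frames` must be a non-empty list.")
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be positive.")
  dims <- lapply(frames, dim)
  d1 <- dims[[1]]
  if (length(d1) != 3 || d1[3] != 3) {
    abort("Each frame must be a height x width x 3 array.")
  }
  if (!all(vapply(dims, identical, logical(1), d1))) {
    abort("All frames must share the same dimensions.")
  }
  structure(list(frames = frames, fps = as.double(fps), t0 = as.double(t0)),
            class = "frame_stack")
}

#' @rdname frame_stack
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, c("frame_stack", "channel_stack")))
  x$t0 + (seq_along(x$frames) - 1) / x$fps
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames, %d x %d px RGB, %g fps, t0 = %g s\n",
              length(x$frames), d[2], d[1], x$fps, x$t0))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' @rdname frame_stack
#' @export
read_video <- function(path, start_s = NULL, end_s = NULL) {
  meta_path <- file.path(path, "frames.json")
  if (!dir.exists(path) || !file.exists(meta_path)) {
    abort(sprintf("'%s' is not a readable frame-sequence directory (frames.json missing).",
                  path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  fps <- meta$fps
  t0 <- meta$t0 %||% 0
  files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.png$", full.names = TRUE))
  if (!length(files)) abort(sprintf("No frame PNGs found in '%s'.", path))
  times <- t0 + (seq_along(files) - 1) / fps
  start_s <- start_s %||% t0
  end_s <- end_s %||% (times[length(times)] + 1 / fps)
  if (start_s >= end_s) abort("Empty interval: start_s must be < end_s.")
  keep <- which(times >= start_s & times < end_s)
  if (!length(keep)) abort("No frames fall inside the requested interval.")
  frames <- lapply(files[keep], function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    array(as.integer(round(a * 255)), dim(a))
  })
  frame_stack(frames, fps = fps, t0 = times[keep[1]])
}

#' @rdname frame_stack
#' @export
write_video <- function(x, path) {
  stopifnot(inherits(x, "frame_stack"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(x$frames)) {
    png::writePNG(x$frames[[i]] / 255,
                  file.path(path, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(list(fps = x$fps, t0 = x$t0, n_frames = length(x$frames)),
                       file.path(path, "frames.json"), auto_unbox = TRUE)
  invisible(path)
}
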