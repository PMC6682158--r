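#' Rectangular region of interest
#'
#' Pixel coordinates are 1-based and inclusive, with `x` indexing columns and
#' `y` indexing rows, so `roi(1, 1, w, h)` covers a whole `h x w` frame. The
#' region should be chosen large enough to contain the full range of motion of
#' the tracked feature but small enough to exclude other followable shapes.
#'
#' @param x0,y0 Upper-left corner (columns, rows; 1-based).
#' @param x1,y1 Lower-right corner (inclusive).
#' @return An `roi` object.
#' @export
roi <- function(x0, y0, x1, y1) {
  if (x0 < 1 || y0 < 1 || x1 < x0 || y1 < y0) {
    abort("Require 1 <= x0 <= x1 and 1 <= y0 <= y1.")
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "roi")
}

#' Extract the green channel from RGB video
#'
#' The green channel has the highest contrast for the near-infrared camera's
#' RGB output, so all downstream tracking runs on it.
#'
#' @param stack A `frame_stack` of RGB frames. A stack whose frames are
#'   already single-channel matrices is passed through with a warning.
#' @return A `channel_stack`: like a `frame_stack` but with one matrix per
#'   frame.
#' @export
extract_green <- function(stack) {
  stopifnot(inherits(stack, c("frame_stack", "channel_stack")))
  if (is.matrix(stack$frames[[1]])) {
    warn("Input is already single-channel; passing through unchanged.")
    return(stack)
  }
  frames <- lapply(stack$frames, function(f) f[, , 2])
  structure(list(frames = frames, fps = stack$fps, t0 = stack$t0),
            class = "channel_stack")
}

#' Threshold an intensity image to binary
#'
#' A pixel is foreground (1) iff its intensity is at or above the threshold.
#' The threshold is deliberately a required, user-chosen parameter: feature
#' contrast varies between animals and markings. [suggest_threshold()] offers
#' Otsu's method as a starting value.
#'
#' @param image A numeric matrix, or a `channel_stack` (each frame is
#'   thresholded).
#' @param threshold Intensity cutoff within the image's value range.
#' @return A logical matrix, or a `binary_stack` of logical matrices.
#' @export
binarize <- function(image, threshold) {
  if (inherits(image, "channel_stack")) {
    frames <- lapply(image$frames, function(f) f >= threshold)
    return(structure(list(frames = frames, fps = image$fps, t0 = image$t0),
                     class = "binary_stack"))
  }
  if (!is.matrix(image)) abort("`image` must be a matrix or channel_stack.")
  image >= threshold
}

#' Suggested binarization threshold (Otsu's method)
#'
#' Convenience helper, not part of the core procedure: returns the threshold
#' maximising between-class variance of an 8-bit intensity histogram, as a
#' starting point for the user's own choice.
#'
#' @param image Numeric matrix with values in 0--255.
#' @return Scalar threshold.
#' @export
suggest_threshold <- function(image) {
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) # threshold value: pixels >= this are foreground
}

# 8-connectivity labeling: EBImage::bwlabel (4-connectivity) completed by
# union-find merging of diagonally adjacent label pairs.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relabel[lab[lab > 0]]
  lab
}

# centroid of each labeled component: tibble(label, area, x, y) in full-frame
# coordinates given the ROI offset
component_centroids <- function(lab, x_off = 0L, y_off = 0L) {
  idx <- which(lab > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(tibble(label = integer(), area = integer(),
                                x = double(), y = double()))
  l <- lab[idx]
  tibble(
    label = sort(unique(l)),
    area = as.integer(tabulate(l)[sort(unique(l))]),
    x = as.double(tapply(idx[, "col"], l, mean)) + x_off,
    y = as.double(tapply(idx[, "row"], l, mean)) + y_off
  )
}

#' Track a followable feature through a binary stack
#'
#' Within the region of interest of every frame, connected components
#' (8-connectivity) of foreground pixels are labeled; one component is chosen
#' by the selection policy and its centroid — the unweighted mean of member
#' pixel coordinates — recorded. Frames whose ROI contains no foreground
#' pixels yield `NA` coordinates (feature absent).
#'
#' Policies: `"largest-area"` (default) picks the biggest component each
#' frame; `"nearest-to-previous"` picks the component whose centroid is
#' closest to the last tracked position, which is more robust when extra
#' followable shapes drift through the ROI.
#'
#' @param stack A `binary_stack` from [binarize()].
#' @param region An [roi()] lying inside the frame.
#' @param selection_policy `"largest-area"` or `"nearest-to-previous"`.
#' @return A `trajectory` tibble: `time_s`, `x_px`, `y_px` (`NA` = absent).
#' @export
track_feature <- function(stack, region,
                          selection_policy = c("largest-area", "nearest-to-previous")) {
  stopifnot(inherits(stack, "binary_stack"), inherits(region, "roi"))
  selection_policy <- match.arg(selection_policy)
  d <- dim(stack$frames[[1]])
  if (region$x1 > d[2] || region$y1 > d[1]) {
    abort(sprintf("ROI (%d..%d, %d..%d) exceeds the %d x %d frame.",
                  region$x0, region$x1, region$y0, region$y1, d[2], d[1]))
  }
  times <- frame_times(structure(stack, class = "channel_stack"))
  n <- length(stack$frames)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  prev <- c(NA_real_, NA_real_)
  for (i in seq_len(n)) {
    sub <- stack$frames[[i]][region$y0:region$y1, region$x0:region$x1, drop = FALSE]
    if (!any(sub)) next
    cc <- component_centroids(label_components(sub),
                              x_off = region$x0 - 1L, y_off = region$y0 - 1L)
    j <- if (selection_policy == "largest-area" || is.na(prev[1])) {
      which.max(cc$area)
    } else {
      which.min((cc$x - prev[1])^2 + (cc$y - prev[2])^2)
    }
    x[i] <- cc$x[j]; y[i] <- cc$y[j]
    prev <- c(x[i], y[i])
  }
  out <- tibble(time_s = times, x_px = x, y_px = y)
  attr(out, "fps") <- stack$fps
  class(out) <- c("trajectory", class(out))
  out
}

# fill NA runs of length <= max_gap samples by linear interpolation;
# longer runs stay NA
fill_short_gaps <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(!is.na(v))
  if (length(ok) < 2) return(v)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    i0 <- starts[k] - 1; i1 <- ends[k] + 1
    if (i0 < 1 || i1 > length(v)) next # edge gaps cannot be interpolated
    idx <- starts[k]:ends[k]
    v[idx] <- v[i0] + (v[i1] - v[i0]) * (idx - i0) / (i1 - i0)
  }
  v
}

#' Estimate breathing frequency by moving-window Fourier analysis
#'
#' For every frame at which a full centered window of the position signal
#' exists, the window is detrended (mean subtraction by default), its discrete
#' Fourier transform taken, and the magnitude spectrum restricted to the
#' search band; the breathing rate is 60 times the frequency of the maximum
#' in-band magnitude ("most prominent peak"). The frequency resolution is one
#' spectral bin, `60 / window_s` breaths per minute.
#'
#' Short runs of absent centroids (up to `max_gap_s`) are bridged by linear
#' interpolation; windows touching longer gaps are flagged undefined (`NA`),
#' as are windows with no in-band power (e.g. a static feature).
#'
#' @param traj A `trajectory` from [track_feature()].
#' @param axis Position signal: `"y"` (default), `"x"`, or `"pc1"` (first
#'   principal axis of the x/y scatter).
#' @param window_s Fourier window length in seconds (default 26).
#' @param band_hz Frequency search band in Hz (default `c(0.2, 5)`, covering
#'   the validated 0.5--4 Hz respiratory range with margin).
#' @param max_gap_s Longest absent-centroid gap bridged by interpolation
#'   (default 0.5 s).
#' @param detrend `"mean"` (default) or `"linear"` per-window detrending.
#' @param interpolate_peak Refine the peak by quadratic interpolation over the
#'   three bins around the maximum? Default `FALSE` (raw bin frequency).
#' @param placement `"centered"` (default, one estimate per frame with a full
#'   centered window) or `"trailing"` (window ends at the frame).
#' @return A `respiration_series` tibble: `time_s`, `bpm`; attributes
#'   `window_s`, `band_hz`, `filters_applied` (empty until [smooth_rate()]).
#' @examples
#' t <- seq(0, 40, by = 1 / 30)
#' traj <- tibble::tibble(time_s = t, x_px = 0, y_px = sin(2 * pi * 2 * t))
#' attr(traj, "fps") <- 30
#' class(traj) <- c("trajectory", class(traj))
#' rs <- estimate_frequency(traj, window_s = 26)
#' unique(rs$bpm) # 120
#' @export
estimate_frequency <- function(traj, axis = c("y", "x", "pc1"), window_s = 26,
                               band_hz = c(0.2, 5), max_gap_s = 0.5,
                               detrend = c("mean", "linear"),
                               interpolate_peak = FALSE,
                               placement = c("centered", "trailing")) {
  check_columns(traj, c("time_s", "x_px", "y_px"), "traj")
  axis <- match.arg(axis)
  detrend <- match.arg(detrend)
  placement <- match.arg(placement)
  fs <- attr(traj, "fps") %||% (1 / median(diff(traj$time_s)))
  n <- nrow(traj)
  if (all(is.na(traj$x_px) & is.na(traj$y_px))) {
    abort("Trajectory is entirely absent; nothing to analyze.")
  }
  sig <- switch(axis,
    y = traj$y_px,
    x = traj$x_px,
    pc1 = {
      ok <- !is.na(traj$x_px) & !is.na(traj$y_px)
      xy <- cbind(traj$x_px, traj$y_px)
      ctr <- colMeans(xy[ok, , drop = FALSE])
      v <- svd(sweep(xy[ok, , drop = FALSE], 2, ctr))$v[, 1]
      as.vector(sweep(xy, 2, ctr) %*% v)
    })
  sig <- fill_short_gaps(sig, max_gap = max(1L, round(max_gap_s * fs)))
  N <- round(window_s * fs)
  if (N < 16) abort("Window too short: need window_s * frame rate >= 16 samples.")
  if (N > n) abort("Window is longer than the trajectory.")
  freqs <- (seq_len(N %/% 2)) * fs / N
  in_band <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (!length(in_band)) abort("No Fourier bins fall inside `band_hz`.")
  half_l <- if (placement == "centered") (N - 1L) %/% 2L else N - 1L
  half_r <- N - 1L - half_l
  valid <- seq.int(1L + half_l, n - half_r)
  bpm <- rep(NA_real_, length(valid))
  w_idx <- seq_len(N)
  for (k in seq_along(valid)) {
    win <- sig[valid[k] - half_l + w_idx - 1L]
    if (anyNA(win)) next
    win <- if (detrend == "mean") win - mean(win)
           else stats::residuals(stats::lm.fit(cbind(1, w_idx), win))
    mag <- Mod(fft(win))[in_band + 1L] # +1: bin 0 is DC
    pk <- which.max(mag)
    if (mag[pk] <= N * 1e-9) next # numerically empty band: undefined
    f_hat <- freqs[in_band[pk]]
    if (interpolate_peak && pk > 1 && pk < length(mag)) {
      a <- mag[pk - 1]; b <- mag[pk]; c <- mag[pk + 1]
      denom <- a - 2 * b + c
      if (abs(denom) > 0) {
        f_hat <- f_hat + 0.5 * (a - c) / denom * (fs / N)
      }
    }
    bpm[k] <- 60 * f_hat
  }
  out <- tibble(time_s = traj$time_s[valid], bpm = bpm)
  attr(out, "window_s") <- window_s
  attr(out, "band_hz") <- band_hz
  attr(out, "filters_applied") <- character()
  class(out) <- c("respiration_series", class(out))
  out
}

# rolling median / mean with shrunken windows at the edges; NAs are ignored
# within a window, all-NA windows return NA
roll_stat <- function(v, half, fun) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (!length(w)) NA_real_ else fun(w)
  }, numeric(1))
}

#' Smooth a breathing-rate series
#'
#' A median filter is applied first to reject isolated artifact spikes (e.g.
#' from a confounding feature entering the ROI for a few windows), followed by
#' a centered moving average (default 800 points, 26 s at 30 fps, matching the
#' per-frame density of [estimate_frequency()] output). Edge windows shrink
#' symmetrically rather than padding.
#'
#' @param series A `respiration_series`.
#' @param median_points Odd median-filter window length (default 31); 1
#'   disables it.
#' @param rolling_points Moving-average window length (default 800); 1
#'   disables it.
#' @return The smoothed `respiration_series`; `filters_applied` records the
#'   parameters.
#' @export
smooth_rate <- function(series, median_points = 31, rolling_points = 800) {
  check_columns(series, c("time_s", "bpm"), "series")
  if (median_points < 1 || rolling_points < 1) {
    abort("Window sizes must be >= 1.")
  }
  if (median_points %% 2 == 0) abort("`median_points` must be odd.")
  bpm <- series$bpm
  if (median_points > 1) bpm <- roll_stat(bpm, (median_points - 1) %/% 2, median)
  if (rolling_points > 1) bpm <- roll_stat(bpm, (rolling_points - 1) %/% 2, mean)
  out <- series
  out$bpm <- bpm
  attr(out, "filters_applied") <- c(attr(series, "filters_applied"),
                                    sprintf("median(%d)", median_points),
                                    sprintf("rolling_mean(%d)", rolling_points))
  out
}

#' Full video-to-breathing-rate pipeline
#'
#' Composition of [extract_green()], [binarize()], [track_feature()],
#' [estimate_frequency()] and [smooth_rate()]. The intermediate trajectory and
#' the unsmoothed per-window peak series are attached as attributes
#' (`trajectory`, `raw_series`) for audit.
#'
#' @param video A `frame_stack` or a path readable by [read_video()].
#' @param region An [roi()].
#' @param threshold Binarization threshold (required, user-chosen).
#' @param window_s,band_hz,axis,selection_policy Passed to the stages.
#' @param median_points,rolling_points Passed to [smooth_rate()].
#' @param ... Further arguments to [estimate_frequency()].
#' @return A smoothed `respiration_series` with audit attributes.
#' @export
respiration_pipeline <- function(video, region, threshold, window_s = 26,
                                 band_hz = c(0.2, 5), axis = "y",
                                 selection_policy = "largest-area",
                                 median_points = 31, rolling_points = 800, ...) {
  stack <- if (is.character(video)) read_video(video) else video
  traj <- track_feature(binarize(extract_green(stack), threshold),
                        region, selection_policy)
  raw <- estimate_frequency(traj, axis = axis, window_s = window_s,
                            band_hz = band_hz, ...)
  out <- smooth_rate(raw, median_points = median_points,
                     rolling_points = rolling_points)
  attr(out, "trajectory") <- traj
  attr(out, "raw_series") <- raw
  out
}

#' Plot a breathing-rate series
#'
#' @param object A `respiration_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.respiration_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$bpm)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Time (s)", y = "Breathing rate (breaths/min)")
}

#' Plot a feature trajectory
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot object of y-position versus time.
#' @export
autoplot.trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$y_px)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Y position (px)")
}
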