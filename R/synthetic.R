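#' Physiology profile for the synthetic generators
#'
#' Bundles the ground-truth trajectories that the synthetic data streams
#' emulate: a circadian activity rate, a torpor-arousal surface-temperature
#' ramp, a breathing-rate profile and a light schedule. Defaults describe a
#' crepuscular/nocturnal hibernator held under "summer" conditions (16 h
#' light / 8 h dark, the day folded so each period starts at dark onset):
#' activity concentrated in the dark phase, surface temperature rising
#' logistically from torpid 23 to aroused 35 Celsius, and breathing rate
#' doubling from 60 to 120 breaths/min over 10 minutes of arousal.
#'
#' @param duration_s Total duration covered by the profile (default 72 h).
#' @param temp_profile_c Function of time (s) returning surface temperature in
#'   Celsius, within 0--45.
#' @param bpm_profile Function of time (s) returning breaths/min, within
#'   0--300.
#' @param activity_rate_profile Function of time (s) returning the motion
#'   event rate in events/min (>= 0).
#' @param light_cycle Data frame with `on_s`, `off_s`: light-phase bounds
#'   within one 86,400-s day.
#' @return A `physiology_profile` list.
#' @export
physiology_profile <- function(duration_s = 72 * 3600,
                               temp_profile_c = NULL,
                               bpm_profile = NULL,
                               activity_rate_profile = NULL,
                               light_cycle = tibble(on_s = 8 * 3600, off_s = 24 * 3600)) {
  temp_profile_c <- temp_profile_c %||%
    function(t) 23 + 12 / (1 + exp(-(t - 300) / 60)) # arousal ramp, 23 -> 35
  bpm_profile <- bpm_profile %||%
    function(t) 60 + 60 * pmin(1, pmax(0, t / 600)) # 60 -> 120 over 10 min
  activity_rate_profile <- activity_rate_profile %||% function(t) {
    tod <- t %% 86400
    # dark phase first (0-8 h): active; light phase (8-24 h): nearly quiescent
    ifelse(tod < 8 * 3600, 6, 0.3)
  }
  structure(list(duration_s = duration_s,
                 temp_profile_c = temp_profile_c,
                 bpm_profile = bpm_profile,
                 activity_rate_profile = activity_rate_profile,
                 light_cycle = light_cycle),
            class = "physiology_profile")
}

# run code with a locally seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a motion event log from an activity-rate profile
#'
#' Draws an inhomogeneous Poisson event stream with intensity
#' `activity_rate_profile(t)` (events/min) by thinning a homogeneous stream at
#' the profile's peak rate. Deterministic for a given seed.
#'
#' @param profile A [physiology_profile()].
#' @param seed Integer seed.
#' @param start_time Experiment start timestamp (default
#'   `"2018-01-01 00:00:00"`).
#' @return A `motion_log`.
#' @export
gen_motion_events <- function(profile, seed,
                              start_time = "2018-01-01 00:00:00") {
  stopifnot(inherits(profile, "physiology_profile"))
  grid <- seq(0, profile$duration_s, length.out = 10001)
  rates <- profile$activity_rate_profile(grid)
  if (any(rates < 0)) abort("Activity rates must be >= 0.")
  lambda_max <- max(rates) / 60 # events per second
  offsets <- with_seed(seed, {
    if (lambda_max == 0) {
      numeric()
    } else {
      n_cand <- stats::rpois(1, lambda_max * profile$duration_s)
      cand <- sort(runif(n_cand, 0, profile$duration_s))
      keep <- runif(n_cand) < profile$activity_rate_profile(cand) / 60 / lambda_max
      cand[keep]
    }
  })
  motion_log(start_time, offsets)
}

#' Generate a stack of thermal frames with known ground truth
#'
#' Renders an elliptical warm body (the animal) on a cooler ambient
#' background, converts temperatures to raw camera units by inverting the
#' supplied linear calibration, adds Gaussian raw-unit noise and quantizes to
#' integers. The default blob covers ~790 pixels, comfortably more than the
#' 480 pixels the brightest-decile rule averages, so the recovered series
#' reflects the blob alone.
#'
#' @param profile A [physiology_profile()]; `temp_profile_c` drives the blob.
#' @param calibration A `thermal_calibration` (or list with `slope`,
#'   `intercept`) to invert; default slope 0.01 deg C/unit, intercept -50.
#' @param blob_geometry List with `cx`, `cy` (center, px) and `rx`, `ry`
#'   (semi-axes, px); must fit in the 80 x 60 frame.
#' @param ambient_c Background temperature (default 22).
#' @param noise_sd Gaussian noise, raw units (default 5).
#' @param n_frames,dt_s Number of frames and frame spacing (defaults 600, 1 s).
#' @param seed Integer seed.
#' @return List with `frames` (list of `thermal_frame`) and `truth` (tibble
#'   `time_s`, `temp_c` of the programmed blob temperature).
#' @export
gen_thermal_stack <- function(profile, calibration = list(slope = 0.01, intercept = -50),
                              blob_geometry = list(cx = 40, cy = 30, rx = 18, ry = 14),
                              ambient_c = 22, noise_sd = 5,
                              n_frames = 600, dt_s = 1, seed = 1) {
  stopifnot(inherits(profile, "physiology_profile"))
  b <- blob_geometry
  if (b$cx - b$rx < 1 || b$cx + b$rx > LEPTON_COLS ||
      b$cy - b$ry < 1 || b$cy + b$ry > LEPTON_ROWS) {
    abort("Blob does not fit inside the 80 x 60 frame.")
  }
  cols <- matrix(seq_len(LEPTON_COLS), LEPTON_ROWS, LEPTON_COLS, byrow = TRUE)
  rows <- matrix(seq_len(LEPTON_ROWS), LEPTON_ROWS, LEPTON_COLS)
  mask <- ((cols - b$cx) / b$rx)^2 + ((rows - b$cy) / b$ry)^2 <= 1
  times <- (seq_len(n_frames) - 1) * dt_s
  temps <- profile$temp_profile_c(times)
  to_raw <- function(tc) (tc - calibration$intercept) / calibration$slope
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    px <- matrix(to_raw(ambient_c), LEPTON_ROWS, LEPTON_COLS)
    px[mask] <- to_raw(temps[i])
    if (noise_sd > 0) px <- px + rnorm(length(px), sd = noise_sd)
    px <- pmin(pmax(round(px), 0), LEPTON_MAX)
    thermal_frame(times[i], px)
  }))
  list(frames = frames, truth = tibble(time_s = times, temp_c = temps))
}

#' Generate a synthetic breathing video with known ground truth
#'
#' A software analogue of an elastic proxy animal on a shaker: a bright green
#' elliptical feature on a dark background whose center oscillates along y
#' with instantaneous frequency `bpm_profile(t) / 60` and the given amplitude,
#' optionally with slow whole-body drift and Gaussian pixel noise. The edge of
#' the feature is rendered with a soft (anti-aliased) profile so the
#' binarized blob's centroid tracks the sub-pixel center position.
#'
#' @param profile A [physiology_profile()]; `bpm_profile` drives the motion.
#' @param duration_s,fps Video length and frame rate (defaults 60 s, 30 fps).
#'   `fps` must satisfy Nyquist: at least twice the maximum programmed
#'   frequency.
#' @param width,height Frame size in pixels (defaults 64 x 64).
#' @param feature List `cx`, `cy`, `rx`, `ry`: mean center and semi-axes (px).
#' @param amplitude_px Oscillation amplitude (>= 0; 0 gives a static feature).
#' @param drift_px_per_s Slow linear drift of the center along x (default 0).
#' @param noise_sd Gaussian pixel noise on 0--255 channels (default 0).
#' @param seed Integer seed.
#' @return List with `stack` (a `frame_stack`), `truth` (tibble `time_s`,
#'   `y_px` programmed center, `bpm` programmed rate).
#' @export
gen_breathing_video <- function(profile, duration_s = 60, fps = 30,
                                width = 64, height = 64,
                                feature = list(cx = width / 2, cy = height / 2,
                                               rx = 7, ry = 5),
                                amplitude_px = 3, drift_px_per_s = 0,
                                noise_sd = 0, seed = 1) {
  stopifnot(inherits(profile, "physiology_profile"))
  if (amplitude_px < 0) abort("`amplitude_px` must be >= 0.")
  n <- round(duration_s * fps)
  times <- (seq_len(n) - 1) / fps
  bpm <- profile$bpm_profile(times)
  if (fps < 2 * max(bpm) / 60) {
    abort(sprintf("Nyquist violation: fps = %g cannot sample %g breaths/min.",
                  fps, max(bpm)))
  }
  # phase = cumulative integral of instantaneous frequency (Hz)
  phase <- cumsum(bpm / 60) / fps
  y_center <- feature$cy + amplitude_px * sin(2 * pi * phase)
  x_center <- feature$cx + drift_px_per_s * times
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  frames <- with_seed(seed, lapply(seq_len(n), function(i) {
    g <- ((cols - x_center[i]) / feature$rx)^2 +
         ((rows - y_center[i]) / feature$ry)^2
    # soft edge ~1 px wide; interior saturates near 255
    green <- 255 * stats::plogis((1 - g) * 6)
    f <- array(0, c(height, width, 3))
    f[, , 1] <- 0.3 * green
    f[, , 2] <- green
    f[, , 3] <- 0.2 * green
    if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)
    array(as.integer(pmin(pmax(round(f), 0), 255)), dim(f))
  }))
  list(stack = frame_stack(frames, fps = fps, t0 = 0),
       truth = tibble(time_s = times, y_px = y_center, bpm = bpm))
}
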