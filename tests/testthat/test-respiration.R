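make_rgb_frame <- function(h, w, r = 0, g = 0, b = 0) {
  f <- array(0L, c(h, w, 3))
  f[, , 1] <- r; f[, , 2] <- g; f[, , 3] <- b
  f
}

test_that("extract_green picks the green channel exactly", {
  stack <- frame_stack(list(make_rgb_frame(8, 10, g = 255)), fps = 30)
  expect_true(all(extract_green(stack)$frames[[1]] == 255))

  red <- frame_stack(list(make_rgb_frame(8, 10, r = 255)), fps = 30)
  expect_true(all(extract_green(red)$frames[[1]] == 0))

  set.seed(20)
  f <- array(sample(0:255, 8 * 10 * 3, replace = TRUE), c(8, 10, 3))
  gs <- extract_green(frame_stack(list(f), fps = 30))
  expect_identical(gs$frames[[1]], f[, , 2])
  expect_warning(extract_green(gs), "single-channel")
})

test_that("binarize thresholds at >= and counts match a direct tally", {
  img <- matrix(128, 6, 6)
  expect_true(all(binarize(img, 100)))
  expect_true(all(binarize(img, 128))) # at threshold: foreground
  m <- matrix(c(254, 10), 4, 4)
  expect_false(any(binarize(m, 255)))
  set.seed(21)
  r <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  expect_equal(sum(binarize(r, 130)), sum(r >= 130))
})

test_that("track_feature centroid equals the brute-force labeling oracle", {
  # single 10x10 square, top-left at column 21, row 31 -> centroid (25.5, 35.5)
  m <- matrix(FALSE, 60, 60)
  m[31:40, 21:30] <- TRUE
  stack <- structure(list(frames = list(m), fps = 30, t0 = 0),
                     class = "binary_stack")
  tr <- track_feature(stack, roi(1, 1, 60, 60))
  expect_equal(tr$x_px, 25.5)
  expect_equal(tr$y_px, 35.5)

  # empty ROI in every frame -> absent
  empty <- structure(list(frames = list(matrix(FALSE, 10, 10)), fps = 30, t0 = 0),
                     class = "binary_stack")
  expect_true(is.na(track_feature(empty, roi(1, 1, 10, 10))$y_px))

  # two blobs: largest-area policy tracks the big one
  m2 <- matrix(FALSE, 30, 30)
  m2[5:14, 5:9] <- TRUE   # 50 px
  m2[20:24, 20:21] <- TRUE # 10 px
  st2 <- structure(list(frames = list(m2), fps = 30, t0 = 0),
                   class = "binary_stack")
  tr2 <- track_feature(st2, roi(1, 1, 30, 30))
  expect_equal(c(tr2$x_px, tr2$y_px), drop(oracle_largest_centroids(m2)))

  # randomized stacks against the oracle, including diagonal-only connections;
  # when several blobs tie for largest area the tracked one must be among them
  set.seed(22)
  for (i in 1:5) {
    mm <- matrix(runif(400) < 0.25, 20, 20)
    stm <- structure(list(frames = list(mm), fps = 30, t0 = 0),
                     class = "binary_stack")
    trm <- track_feature(stm, roi(1, 1, 20, 20))
    o <- oracle_largest_centroids(mm)
    if (is.null(o)) {
      expect_true(is.na(trm$x_px))
    } else {
      dists <- sqrt((o[, 1] - trm$x_px)^2 + (o[, 2] - trm$y_px)^2)
      expect_lt(min(dists), 1e-10)
    }
  }
  expect_error(track_feature(st2, roi(1, 1, 40, 40)), "exceeds")
})

test_that("nearest-to-previous policy sticks with the tracked feature", {
  # frame 1: only feature A; frame 2: A moved slightly + larger distractor B
  a1 <- matrix(FALSE, 30, 30); a1[10:13, 10:13] <- TRUE
  a2 <- matrix(FALSE, 30, 30); a2[11:14, 10:13] <- TRUE; a2[22:29, 20:27] <- TRUE
  st <- structure(list(frames = list(a1, a2), fps = 30, t0 = 0),
                  class = "binary_stack")
  near <- track_feature(st, roi(1, 1, 30, 30), "nearest-to-previous")
  expect_equal(near$y_px[2], mean(11:14))
  big <- track_feature(st, roi(1, 1, 30, 30), "largest-area")
  expect_equal(big$y_px[2], mean(22:29))
})

test_that("estimate_frequency recovers pure and mixed sinusoids", {
  fs <- 30
  t <- (0:(40 * fs - 1)) / fs
  # 2 Hz -> 120 bpm at every output point
  rs <- estimate_frequency(make_traj(sin(2 * pi * 2 * t), fs), window_s = 26)
  expect_true(all(abs(rs$bpm - 120) <= 60 / 26))

  # amplitude 1.0 at 1 Hz + 0.2 at 3 Hz -> the larger component wins: 60 bpm
  mix <- sin(2 * pi * t) + 0.2 * sin(2 * pi * 3 * t)
  rs2 <- estimate_frequency(make_traj(mix, fs), window_s = 26)
  expect_true(all(abs(rs2$bpm - 60) <= 60 / 26))

  # constant trajectory: no in-band peak -> flagged undefined
  rs3 <- estimate_frequency(make_traj(rep(5, 40 * fs), fs), window_s = 26)
  expect_true(all(is.na(rs3$bpm)))

  expect_error(estimate_frequency(make_traj(sin(t[1:100]), fs), window_s = 26),
               "longer than")
  all_na <- make_traj(rep(NA_real_, 900), fs, x = NA_real_)
  expect_error(estimate_frequency(all_na), "entirely absent")
})

test_that("frequency estimate is invariant to offset and linear drift", {
  fs <- 30
  t <- (0:(35 * fs - 1)) / fs
  y <- sin(2 * pi * 1.5 * t)
  base <- estimate_frequency(make_traj(y, fs), window_s = 26)
  shifted <- estimate_frequency(make_traj(y + 400, fs), window_s = 26)
  expect_equal(base$bpm, shifted$bpm)
  drifted <- estimate_frequency(make_traj(y + 0.05 * t, fs), window_s = 26,
                                detrend = "linear")
  expect_equal(base$bpm, drifted$bpm)
})

test_that("short centroid gaps are bridged, long gaps flag windows undefined", {
  fs <- 30
  t <- (0:(35 * fs - 1)) / fs
  y <- sin(2 * pi * 2 * t)
  y[300:305] <- NA # 0.2 s gap: bridged
  rs <- estimate_frequency(make_traj(y, fs), window_s = 20)
  expect_false(anyNA(rs$bpm))
  y2 <- sin(2 * pi * 2 * t)
  y2[300:360] <- NA # 2 s gap: windows covering it are undefined
  rs2 <- estimate_frequency(make_traj(y2, fs), window_s = 20)
  expect_true(anyNA(rs2$bpm))
  expect_false(all(is.na(rs2$bpm)))
})

test_that("smooth_rate applies median-then-mean with shrunken edge windows", {
  const <- structure(tibble::tibble(time_s = 1:50, bpm = 90),
                     class = c("respiration_series", class(tibble::tibble())))
  sm <- smooth_rate(const, 5, 7)
  expect_equal(sm$bpm, rep(90, 50))

  spiked <- const
  spiked$bpm[25] <- 400
  desp <- smooth_rate(spiked, 5, 1)
  expect_equal(desp$bpm, rep(90, 50))

  expect_error(smooth_rate(const, 4, 7), "odd")
  expect_error(smooth_rate(const, 0, 7), ">= 1")

  # random series vs sequential brute-force median-then-mean with shrinking edges
  set.seed(23)
  r <- const
  r$bpm <- rnorm(50, 100, 20)
  got <- smooth_rate(r, 5, 9)
  med <- vapply(1:50, function(i) median(r$bpm[max(1, i - 2):min(50, i + 2)]),
                numeric(1))
  man <- vapply(1:50, function(i) mean(med[max(1, i - 4):min(50, i + 4)]),
                numeric(1))
  expect_equal(got$bpm, man)
})

test_that("full pipeline recovers a programmed constant rate from video", {
  p <- physiology_profile(bpm_profile = function(t) rep(120, length(t)))
  bv <- gen_breathing_video(p, duration_s = 35, fps = 30, seed = 31)
  rs <- respiration_pipeline(bv$stack, roi(10, 10, 55, 55), threshold = 128,
                             rolling_points = 51)
  expect_true(all(abs(rs$bpm - 120) <= 60 / 26))
  # audit artifacts attached
  expect_s3_class(attr(rs, "trajectory"), "trajectory")
  expect_s3_class(attr(rs, "raw_series"), "respiration_series")
})

test_that("a static feature yields an undefined-frequency flag", {
  p <- physiology_profile(bpm_profile = function(t) rep(120, length(t)))
  bv <- gen_breathing_video(p, duration_s = 25, fps = 30, amplitude_px = 0,
                            seed = 32)
  traj <- track_feature(binarize(extract_green(bv$stack), 128),
                        roi(10, 10, 55, 55))
  rs <- estimate_frequency(traj, window_s = 20)
  expect_true(all(is.na(rs$bpm)))
})

test_that("suggest_threshold separates a bimodal image", {
  set.seed(24)
  img <- matrix(c(rnorm(300, 40, 8), rnorm(100, 220, 8)), 20, 20)
  img <- pmin(pmax(round(img), 0), 255)
  th <- suggest_threshold(img)
  expect_true(th > 60 && th < 210)
})
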