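test_that("top_fraction_mean averages exactly the k brightest pixels", {
  const <- thermal_frame(0, matrix(4242, 60, 80))
  expect_equal(top_fraction_mean(const, 0.1), 4242)
  expect_equal(top_fraction_mean(const, 0.73), 4242)

  # 480 bright pixels exactly fill the default decile
  px <- matrix(1000, 60, 80)
  px[seq_len(480)] <- 9000
  expect_equal(top_fraction_mean(thermal_frame(0, px), 0.10), 9000)

  # randomized frames vs explicit sort-descending-take-k oracle
  set.seed(13)
  for (i in 1:5) {
    f <- thermal_frame(0, matrix(sample(0:16383, 4800, replace = TRUE), 60, 80))
    for (fr in c(0.03, 0.10, 0.5, 1)) {
      k <- round(fr * 4800)
      expect_equal(top_fraction_mean(f, fr),
                   mean(sort(as.double(f$pixels), decreasing = TRUE)[1:k]))
    }
  }
  expect_error(top_fraction_mean(const, 0), "fraction")
  expect_error(top_fraction_mean(const, 1.5), "fraction")
})

test_that("top_fraction_mean is monotone in fraction and ignores background", {
  set.seed(14)
  f <- thermal_frame(0, matrix(sample(2000:12000, 4800, replace = TRUE), 60, 80))
  fr <- c(0.05, 0.1, 0.3, 0.7, 1)
  m <- vapply(fr, function(x) top_fraction_mean(f, x), numeric(1))
  expect_true(all(diff(m) <= 0))
  expect_equal(top_fraction_mean(f, 1), mean(f$pixels))

  # changing pixels outside the top-k set leaves the mean unchanged
  px <- f$pixels
  cutoff <- sort(as.double(px), decreasing = TRUE)[480]
  px[px < cutoff - 1] <- 0
  expect_equal(top_fraction_mean(thermal_frame(0, px), 0.1),
               top_fraction_mean(f, 0.1))
})

test_that("fit_calibration matches the closed-form least-squares solution", {
  u <- c(7000, 7500, 8000, 8500)
  cal <- fit_calibration(raw = u, temp_c = 0.01 * u - 50)
  expect_equal(cal$slope, 0.01)
  expect_equal(cal$intercept, -50)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$n_points, 4L)

  expect_error(fit_calibration(raw = 7000, temp_c = 20), "at least 2")
  expect_error(fit_calibration(raw = c(7000, 7000), temp_c = c(20, 25)),
               "identical")

  set.seed(15)
  for (i in 1:5) {
    x <- runif(20, 6000, 9000)
    y <- 0.012 * x - 55 + rnorm(20, sd = 0.5)
    cal <- fit_calibration(raw = x, temp_c = y)
    o <- oracle_ols(x, y)
    expect_equal(cal$slope, unname(o["slope"]), tolerance = 1e-9)
    expect_equal(cal$intercept, unname(o["intercept"]), tolerance = 1e-9)
  }
})

test_that("calibration tidy/glance and JSON round trip preserve the fit", {
  cal <- fit_calibration(raw = c(7000, 7500, 8100), temp_c = c(20.1, 25.2, 31))
  td <- tidy(cal)
  expect_equal(td$estimate, c(cal$intercept, cal$slope))
  expect_equal(glance(cal)$nobs, 3L)

  p <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, p)
  back <- read_calibration_json(p)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(back$r_squared, cal$r_squared)
})

test_that("frames_to_temperature applies the calibration per frame", {
  cal <- structure(list(slope = 0.01, intercept = -50),
                   class = "thermal_calibration")
  frames <- lapply(0:4, function(t) thermal_frame(t, matrix(8000, 60, 80)))
  ts <- frames_to_temperature(frames, cal)
  expect_equal(ts$temp_c, rep(30, 5))

  ident <- structure(list(slope = 1, intercept = 0),
                     class = "thermal_calibration")
  raw_means <- vapply(frames, top_fraction_mean, numeric(1))
  expect_equal(frames_to_temperature(frames, ident)$temp_c, raw_means)

  expect_error(frames_to_temperature(rev(frames), cal), "ordered")
})

test_that("temperature readout is affine-equivariant under raw-unit rescaling", {
  set.seed(16)
  px <- matrix(sample(6000:9000, 4800, replace = TRUE), 60, 80)
  f <- thermal_frame(0, px)
  cal <- structure(list(slope = 0.01, intercept = -50),
                   class = "thermal_calibration")
  t1 <- frames_to_temperature(list(f), cal)$temp_c
  # u -> 0.5 u + 1000 with the matching transformed calibration
  f2 <- thermal_frame(0, 0.5 * px + 1000)
  cal2 <- structure(list(slope = cal$slope / 0.5,
                         intercept = cal$intercept - cal$slope * 1000 / 0.5),
                    class = "thermal_calibration")
  t2 <- frames_to_temperature(list(f2), cal2)$temp_c
  expect_equal(t1, t2, tolerance = 1e-3) # integer quantization of raw units
})

test_that("mean_abs_deviation handles paired series and precomputed deviations", {
  expect_equal(mean_abs_deviation(c(30, 31), c(30, 31)), 0)
  set.seed(17)
  a <- rnorm(40, 33); b <- rnorm(40, 33)
  manual <- mean(abs(a - b))
  expect_equal(mean_abs_deviation(a, b), manual)
  expect_equal(mean_abs_deviation(deviations = abs(a - b)), manual)
  expect_error(mean_abs_deviation(1:3, 1:2), "equal length")
})

test_that("blob smaller than the decile biases the readout toward background", {
  profile <- physiology_profile(temp_profile_c = function(t) rep(35, length(t)))
  small <- gen_thermal_stack(profile,
                             blob_geometry = list(cx = 40, cy = 30, rx = 6, ry = 5),
                             noise_sd = 0, n_frames = 3, seed = 2)
  cal <- structure(list(slope = 0.01, intercept = -50),
                   class = "thermal_calibration")
  temps <- frames_to_temperature(small$frames, cal)$temp_c
  expect_true(all(temps < 35))
  expect_true(all(temps > 22)) # but above ambient: mixture of blob + background
})
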