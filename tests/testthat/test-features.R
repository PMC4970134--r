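test_that("calibration subtracts the baseline-window mean per sensor", {
  # constant signal: calibrated trace is identically zero
  rec <- toy_recording(rep(2.5, 10))
  expect_equal(unname(calibrate(rec)[, 1]), rep(0, 10))

  # baseline = mean of the first two points
  rec <- toy_recording(c(1, 1, 3, 5))
  expect_equal(unname(calibrate(rec)[, 1]), c(0, 0, 2, 4))

  # sinusoid plus offset: calibrated signal has zero mean over the window
  t <- seq(0, 4 * pi, length.out = 200)
  v <- 3 + sin(t)
  rec <- toy_recording(v, baseline_window = 1:50)
  expect_equal(mean(calibrate(rec)[1:50, 1]), 0)
})

test_that("recording construction rejects invalid inputs", {
  expect_error(sensor_recording(matrix(1, 1, 1), 2), "2 time steps")
  expect_error(sensor_recording(matrix(1, 5, 1), 0), "positive")
  expect_error(sensor_recording(matrix(1, 5, 1), 2, baseline_window = integer(0)),
               "baseline_window")
  expect_error(sensor_recording(matrix(1, 5, 1), 2, baseline_window = 9),
               "baseline_window")
})

test_that("peak and integral features match closed forms", {
  expect_equal(feature_vmax(c(0, 2, -5, 1)), 5)
  expect_equal(feature_vmax(rep(0, 4)), 0)
  v_rise <- cumsum(runif(50)) # monotone rising from positive steps
  expect_equal(feature_vmax(v_rise), v_rise[50])

  expect_equal(feature_vint(rep(0, 10), 0.5), 0)
  # constant c over T seconds: trapezoid gives c * T exactly on a uniform grid
  n <- 11
  dt <- 0.5
  expect_equal(feature_vint(rep(3, n), dt), 3 * (n - 1) * dt)
  # linear ramp 0 -> 1 over T seconds integrates to T / 2
  T_total <- 5
  v <- seq(0, 1, length.out = 101)
  expect_equal(feature_vint(v, T_total / 100), T_total / 2)
})

test_that("EMA derivative features follow the recursion", {
  expect_equal(unname(ema_derivative_features(rep(0, 20), 10)), rep(0, 6))

  # at SR = 1 the largest smoothing factor is a = 1 and the recursion
  # collapses to first differences (with y(1) = V(1))
  v <- c(0.3, 1.1, 0.2, 0.9, 0.4)
  f <- ema_derivative_features(v, 1)
  d <- c(v[1], diff(v))
  expect_equal(unname(f[c("ema_a1_min", "ema_a1_max")]), c(min(d), max(d)))

  # unit step of height h: y jumps to a * h at the step, then decays
  # geometrically, so the max is exactly a * h and the min is 0
  h <- 2
  v <- c(rep(0, 10), rep(h, 30))
  sr <- 2
  f <- ema_derivative_features(v, sr)
  for (nm in c("a100", "a10", "a1")) {
    a <- switch(nm, a100 = 1 / (100 * sr), a10 = 1 / (10 * sr), a1 = 1 / sr)
    expect_equal(unname(f[paste0("ema_", nm, "_max")]), a * h)
    expect_equal(unname(f[paste0("ema_", nm, "_min")]), 0)
  }

  expect_error(ema_derivative_features(c(1, 2), 0), "positive")
  expect_error(ema_derivative_features(c(1, 2), 0.5), "smoothing factor")
})

test_that("EMA output is bounded by the largest first difference", {
  set.seed(42)
  for (rep_i in 1:20) {
    v <- cumsum(rnorm(100))
    sr <- sample(c(1, 2, 10), 1)
    f <- ema_derivative_features(v, sr)
    bound <- max(abs(diff(v))) + abs(v[1]) # a <= 1
    expect_true(all(abs(f) <= bound + 1e-12))
  }
})

test_that("feature vectors have stable length, names and offset invariance", {
  spec <- synthetic_spec(n_classes = 2, n_sensors = 16, n_per_class = 1,
                         total_s = 60, response_s = 30, baseline_s = 10, seed = 7)
  rec <- generate_recordings(spec)[[1]]
  fv <- extract_features(rec)
  expect_length(fv, 16 * 8)
  expect_identical(names(fv)[1:2], c("sensor_1_vmax", "sensor_1_vint"))
  # names are deterministic across repeated extraction
  expect_identical(names(fv), names(extract_features(rec)))

  one <- sensor_recording(matrix(sin(1:50), ncol = 1), 2, baseline_window = 1:5)
  expect_length(extract_features(one), 8)

  zero <- sensor_recording(matrix(0, 40, 3), 2, baseline_window = 1:5)
  expect_equal(unname(extract_features(zero)), rep(0, 24))

  # a constant per-sensor offset captured by the baseline window cancels
  shifted <- sensor_recording(rec$readings + 1.5, rec$sampling_rate,
                              rec$baseline_window, rec$sample_id)
  expect_equal(extract_features(shifted), extract_features(rec))
})

test_that("min-max scaler maps training data to [0,1] and clips test data", {
  x <- cbind(a = c(2, 4, 6), b = c(3, 3, 3))
  sc <- fit_scaler(x)
  xs <- apply_scaler(x, sc)
  expect_equal(unname(xs[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(xs[, "b"]), c(0, 0, 0)) # constant column maps to 0
  expect_equal(unname(apply_scaler(c(a = 8, b = 3), sc)), c(1, 0)) # clipped

  set.seed(11)
  xr <- matrix(rnorm(200), 20)
  ss <- apply_scaler(xr, fit_scaler(xr))
  expect_true(all(ss >= 0 & ss <= 1))
  expect_equal(unname(apply(ss, 2, min)), rep(0, 10))
  expect_equal(unname(apply(ss, 2, max)), rep(1, 10))
})
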