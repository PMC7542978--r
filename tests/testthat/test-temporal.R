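test_that("spectrum peak finds the fundamental", {
  t <- (0:799) / 50
  sp <- component_spectrum(sin(2 * pi * 1 * t), 50)
  expect_equal(sp$peak_freq, 1.0, tolerance = 0.0625)
  expect_equal(max(sp$power), 1)
  # dominant 1 Hz with a weak 3 Hz rider
  sp2 <- component_spectrum(sin(2 * pi * t) + 0.3 * sin(2 * pi * 3 * t), 50)
  expect_equal(sp2$peak_freq, 1.0, tolerance = 0.0625)
  expect_error(component_spectrum(rep(2, 800)), "constant")
})

test_that("generator spectrum peaks at the spec frequency (noiseless)", {
  spec <- synthetic_spec(noise_sd = 0, freq_jitter_sd = 0,
                         loading_jitter_sd = 0, n_subjects = 1, n_runs = 1,
                         seed = 3)
  d <- decompose_run(simulate_runs(spec)$runs[[1]])
  sp <- component_spectrum(d$time_courses[, 1], 50)
  expect_equal(sp$peak_freq, spec$base_freq, tolerance = 0.0625 + 1e-12)
})

test_that("component_delay recovers constructed shifts", {
  t <- (0:799) / 50
  a <- harmonic_pulse(t, 1)
  expect_equal(component_delay(a, a), 0L)
  b <- c(rep(a[1], 10), a[1:(length(a) - 10)])  # b lags a by 10 frames
  expect_equal(component_delay(a, b, 25), 10L)
  expect_equal(component_delay(b, a, 25), -10L)
  # 30-frame shift aliases to -20 under the 25-frame cap (period 50)
  b30 <- c(rep(a[1], 30), a[1:(length(a) - 30)])
  expect_equal(component_delay(a, b30, 25), -20L)
  expect_error(component_delay(a, rep(1, 800)), "zero-variance")
})

test_that("delay antisymmetry holds for unique optima", {
  set.seed(12)
  for (i in 1:10) {
    a <- smooth_series(300)
    b <- smooth_series(300)
    d1 <- component_delay(a, b, 25)
    d2 <- component_delay(b, a, 25)
    if (abs(d1) != abs(d2)) next  # tie at equal |lag| is the documented exception
    expect_equal(d1, -d2)
  }
})

test_that("gaiting fraction counts delays inside the window", {
  expect_equal(gaiting_fraction(rep(0, 12)), 1.0)
  expect_equal(gaiting_fraction(c(10, -30, 55), 50), 2 / 3)
  expect_error(gaiting_fraction(integer()), "undefined")
  prof <- delay_profile(c(10, -30, 55), 50)
  expect_equal(prof$within_window_fraction, 2 / 3)
})

test_that("FIR low-pass preserves the passband and kills the stopband", {
  t <- (0:799) / 50
  x <- sin(2 * pi * 1 * t)
  y <- fir_lowpass(x, 50, 10)
  expect_equal(y[100:700], x[100:700], tolerance = 0.01)
  hi <- sin(2 * pi * 25 * t + 0.4)
  expect_lt(max(abs(fir_lowpass(hi, 50, 10)[100:700])), 0.05)
  # peak count of a band-limited pulse train is unchanged
  p <- harmonic_pulse(t, 1)
  r <- diff(range(p))
  expect_equal(length(find_peaks(fir_lowpass(p, 50, 10), 30, 0.1 * r)),
               length(find_peaks(p, 30, 0.1 * r)))
})

test_that("sensor_frequency matches constructed rates", {
  t <- (0:799) / 50
  x <- harmonic_pulse(t, 1)
  expect_equal(sensor_frequency(x, 50), 1.0, tolerance = 0.01)
  x05 <- harmonic_pulse(t, 0.5)
  expect_equal(sensor_frequency(x05, 50), 0.5, tolerance = 0.01)
  set.seed(14)
  noisy <- x + rnorm(800, 0, 0.05 * diff(range(x)))
  expect_equal(suppressWarnings(sensor_frequency(noisy, 50)), 1.0,
               tolerance = 0.05)
  expect_error(sensor_frequency(rep(c(0, 1e-9), 10), 50), "maxima")
})

test_that("group frequency tests: power and degenerate cases", {
  set.seed(15)
  mk <- function(hand, shift) do.call(rbind, lapply(1:50, function(r)
    data.frame(subject_id = "S01", run_index = r, hand = hand,
               group = c("Thumb", "MCP", "PIP"),
               freq = rnorm(3, 1 + shift, 0.05))))
  tab <- rbind(mk("left", 0), mk("right", 0.2))
  res <- group_frequency_tests(tab)
  expect_true(all(res$between_p < 0.001))
  # identical values in two runs per hand: Friedman cannot discriminate
  tab2 <- do.call(rbind, lapply(c("left", "right"), function(h)
    do.call(rbind, lapply(1:2, function(r)
      data.frame(subject_id = "S01", run_index = r, hand = h,
                 group = c("Thumb", "MCP", "PIP"), freq = 1.0)))))
  res2 <- suppressWarnings(group_frequency_tests(tab2))
  expect_true(all(is.na(res2$friedman_p) | res2$friedman_p > 0.9))
})

test_that("between-hand test is calibrated under the null", {
  set.seed(16)
  mk <- function(hand) do.call(rbind, lapply(1:20, function(r)
    data.frame(subject_id = "S01", run_index = r, hand = hand,
               group = "MCP", freq = rnorm(1, 1, 0.1))))
  rej <- replicate(200, {
    res <- group_frequency_tests(rbind(mk("left"), mk("right")))
    res$between_p[["MCP"]] < 0.05
  })
  expect_lt(mean(rej), 0.12)
  expect_gt(mean(rej), 0.005)
})
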