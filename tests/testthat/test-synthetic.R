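test_that("same seed gives identical output, different seed differs", {
  a <- simulate_runs(small_spec(seed = 5))
  b <- simulate_runs(small_spec(seed = 5))
  expect_identical(a$runs[[1]]$data, b$runs[[1]]$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_runs(small_spec(seed = 6))
  expect_false(identical(a$runs[[1]]$data, c$runs[[1]]$data))
})

test_that("emitted runs respect the declared shape and range", {
  sim <- simulate_runs(small_spec(n_subjects = 1, n_runs = 2))
  for (run in sim$runs) {
    expect_equal(dim(run$data), c(800, 19))
    expect_true(all(run$data >= 0 & run$data <= 1000))
    expect_identical(colnames(run$data), default_layout()$relevant19)
  }
})

test_that("single noiseless component yields a rank-1 run", {
  spec <- synthetic_spec(n_components = 1, amplitudes = 1, delays_s = 0,
                         noise_sd = 0, loading_jitter_sd = 0,
                         n_subjects = 1, n_runs = 1, seed = 2)
  run <- simulate_runs(spec)$runs[[1]]
  d <- suppressWarnings(decompose_run(run))  # zero-loading channels are constant
  expect_gt(d$var_fraction[1], 0.999)
  # every channel a scalar multiple of one waveform
  R <- sweep(run$data, 2, colMeans(run$data))
  expect_lt(qr(R, tol = 1e-7)$rank, 2 + 1)
})

test_that("PCA recovers orthogonal loadings exactly at zero noise", {
  spec <- synthetic_spec(noise_sd = 0, freq_jitter_sd = 0,
                         loading_jitter_sd = 0, n_subjects = 1, n_runs = 1,
                         seed = 4)
  d <- decompose_run(simulate_runs(spec)$runs[[1]])
  for (k in 1:3)
    expect_gt(abs(sum(d$ecs[, k] * spec$loadings[k, ])), 0.999)
})

test_that("variance-fraction ranking matches amplitude ranking at zero noise", {
  spec <- synthetic_spec(noise_sd = 0, loading_jitter_sd = 0,
                         freq_jitter_sd = 0,
                         n_subjects = 1, n_runs = 1, seed = 9)
  d <- decompose_run(simulate_runs(spec)$runs[[1]])
  # component k's variance share is proportional to amplitude_k^2
  expect_equal(order(d$var_fraction[1:3], decreasing = TRUE), 1:3)
  expect_equal(d$var_fraction[1] / d$var_fraction[2],
               (spec$amplitudes[1] / spec$amplitudes[2])^2, tolerance = 1e-6)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(delays_s = c(0, 0.5, 1.0)), "\\[0, 1\\)")
  bad <- default_loadings()
  bad[1, ] <- bad[1, ] * 2
  expect_error(synthetic_spec(loadings = bad), "unit")
  expect_error(synthetic_spec(amplitudes = c(1, 1, 0.5)), "decreasing")
})

test_that("stock loadings are orthonormal with the documented structure", {
  for (L in list(default_loadings(), module_loadings())) {
    expect_equal(L %*% t(L), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  L <- default_loadings()
  expect_gt(L[1, "Tcross"], 0)
  expect_gt(L[1, "PArch"], 0)
  expect_true(all(L[1, c("PIP_I", "PIP_M", "PIP_R", "PIP_L")] < 0))
  expect_true(all(L[2, c("MCP_I", "MCP_M", "PIP_I", "PIP_M")] > 0))
  expect_lt(L[2, "MCP_T"], 0)  # thumb bends out of phase in component 2
  expect_lt(L[2, "PIP_T"], 0)
})

test_that("circular tip trajectories have the analytic speed", {
  s <- simulate_trajectory(1, radii_cm = 2, n_frames = 370, rate = 36.97,
                           noise_mm = 0, seed = 1)
  xyz <- s$coords[, s$tip_points[2], ]
  # mean speed over an integer number of cycles ~ circumference * freq
  v <- sqrt(rowSums(diff(xyz)^2)) * s$rate / 10  # cm/s
  expect_equal(mean(v), 2 * pi * 2 * 1, tolerance = 0.01)
  # zero radius -> zero speed
  s0 <- simulate_trajectory(1, radii_cm = 0, n_frames = 100, noise_mm = 0, seed = 1)
  expect_equal(max(abs(diff(s0$coords[, s0$tip_points[1], ]))), 0)
})

test_that("trajectory generator guards against aliasing and repeats", {
  expect_error(simulate_trajectory(20, rate = 36.97), "alias")
  a <- simulate_trajectory(1, noise_mm = 1, seed = 8)
  b <- simulate_trajectory(1, noise_mm = 1, seed = 8)
  expect_identical(a$coords, b$coords)
})

test_that("thumb extension has one detectable maximum per cycle", {
  s <- simulate_trajectory(1, radii_cm = 2, n_frames = 370, rate = 36.97,
                           noise_mm = 0, seed = 5)
  segs <- segment_trajectories(s)
  expect_true(length(segs[[1]]) %in% 8:10)  # ~9 for 10 s at 1 Hz
})
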