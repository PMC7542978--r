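test_that("full decomposition reconstructs the residual matrix", {
  set.seed(21)
  run <- run_from_signal(matrix(rnorm(800 * 19), 800, 19))
  d <- decompose_run(run)
  R <- sweep(run$data, 2, colMeans(run$data))
  recon <- d$time_courses %*% (d$singvals * t(d$ecs))
  expect_lt(norm(recon - R, "F") / norm(R, "F"), 1e-8)
  # orthonormality and variance accounting
  expect_equal(crossprod(d$ecs), diag(19), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(d$var_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(d$eigenvalues) <= 1e-12))
})

test_that("three-component synthetic runs concentrate variance on top", {
  sim <- simulate_runs(small_spec(n_subjects = 1, n_runs = 3, seed = 31))
  for (run in sim$runs) {
    d <- decompose_run(run)
    expect_gt(sum(d$var_fraction[1:3]), 0.95)
    expect_equal(guttman_kaiser(d), 3)
  }
})

test_that("degenerate inputs are flagged", {
  m <- matrix(runif(10 * 19, 400, 600), 10, 19,
              dimnames = list(NULL, default_layout()$relevant19))
  expect_error(decompose_run(sensor_run(m[1:5, ])), "fewer frames")
  m2 <- matrix(runif(50 * 2, 400, 600), 50, 2,
               dimnames = list(NULL, c("MCP_T", "MCP_I")))
  m2[, 2] <- 500
  expect_warning(decompose_run(sensor_run(m2)), "zero-variance")
})

test_that("Guttman-Kaiser counts eigenvalues above the mean", {
  expect_equal(guttman_kaiser(c(10, 5, 2, 1, 1, 1)), 2)  # mean 3.33
  expect_equal(guttman_kaiser(rep(4, 7)), 0)             # none strictly above
  spec <- synthetic_spec(n_components = 1, amplitudes = 1, delays_s = 0,
                         noise_sd = 0, loading_jitter_sd = 0,
                         n_subjects = 1, n_runs = 1, seed = 1)
  d <- suppressWarnings(decompose_run(simulate_runs(spec)$runs[[1]]))
  expect_equal(guttman_kaiser(d), 1)
})

make_decomp <- function(ec, subject = "S01", run = 1L) {
  # minimal decomposition stub for alignment tests
  structure(list(ecs = matrix(ec, ncol = 1,
                              dimnames = list(names(ec), NULL)),
                 time_courses = matrix(0, 4, 1), singvals = 1,
                 eigenvalues = 1, var_fraction = 1,
                 run_ref = list(subject_id = subject, hand = "right",
                                run_index = run)),
            class = "decomposition")
}

test_that("within-subject alignment recovers corrupted signs exactly", {
  set.seed(7)
  v <- rnorm(19)
  signs <- c(1, -1, 1, 1, -1, 1)  # runs 2 and 5 negated
  ds <- lapply(seq_along(signs), function(i)
    make_decomp(v * signs[i], run = i))
  flips <- align_within_subject(ds, 1)
  aligned <- sapply(seq_along(ds), function(i) ds[[i]]$ecs[, 1] * flips[i])
  C <- cor(aligned)
  expect_true(all(abs(C - 1) < 1e-12))
})

test_that("orthogonal ECs leave alignment at identity; single run trivial", {
  # zero-mean mutually orthogonal patterns: pairwise Pearson r is exactly 0
  v1 <- rep(c(1, -1), 4)
  v2 <- rep(c(1, 1, -1, -1), 2)
  v3 <- c(rep(1, 4), rep(-1, 4))
  v <- cbind(v1, v2, v3, v1 * v2)
  ds <- lapply(1:4, function(i) make_decomp(v[, i], run = i))
  expect_equal(align_within_subject(ds, 1), rep(1L, 4))
  expect_equal(align_within_subject(ds[1], 1), 1L)
})

test_that("alignment restores the pre-corruption mean pairwise correlation", {
  set.seed(13)
  base <- rnorm(19)
  clean <- t(sapply(1:6, function(i) base + rnorm(19, 0, 0.3)))
  obj <- function(m) mean(cor(t(m))[upper.tri(diag(6))])
  r_clean <- obj(clean)
  corrupt <- clean * sample(c(-1, 1), 6, replace = TRUE)
  ds <- lapply(1:6, function(i) make_decomp(corrupt[i, ], run = i))
  flips <- align_within_subject(ds, 1)
  expect_equal(obj(corrupt * flips), r_clean, tolerance = 1e-12)
})

test_that("across-subject alignment and the canonical sign rule", {
  set.seed(17)
  v <- rnorm(19)
  names(v) <- default_layout()$relevant19
  means <- t(sapply(c(1, -1, 1, -1, -1), function(s) s * v))
  flips <- align_across_subjects(means)
  aligned <- means * flips
  expect_true(all(abs(cor(t(aligned)) - 1) < 1e-12))
  # canonical rule: summed loading over thumb-cross + finger MCP/PIP > 0
  canon <- c("Tcross", "MCP_I", "MCP_M", "MCP_R", "MCP_L",
             "PIP_I", "PIP_M", "PIP_R", "PIP_L")
  expect_gt(sum(colMeans(aligned)[canon]), 0)
  # an EC negative on those channels comes back negated
  neg <- matrix(-abs(rnorm(19)), 1, dimnames = list(NULL, names(v)))
  expect_equal(align_across_subjects(neg), -1L)
})

test_that("alignment objective beats 1000 random sign assignments", {
  set.seed(23)
  sim <- simulate_runs(small_spec(n_subjects = 6, n_runs = 1, seed = 23))
  ds <- lapply(sim$runs, decompose_run)
  means <- t(sapply(ds, function(d) d$ecs[, 1]))
  colnames(means) <- default_layout()$relevant19
  flips <- align_across_subjects(means)
  C <- cor(t(means))
  obj <- function(s) {
    M <- C * tcrossprod(s)
    sum(M[upper.tri(M)])
  }
  achieved <- obj(flips)
  rand <- replicate(1000, obj(sample(c(-1, 1), 6, replace = TRUE)))
  expect_true(all(achieved >= rand - 1e-12))
})

test_that("flips never change eigenvalues or the reconstruction", {
  sim <- simulate_runs(small_spec(n_subjects = 2, n_runs = 3, seed = 29))
  ds <- lapply(sim$runs, decompose_run)
  aset <- align_cohort(ds)
  for (i in seq_along(ds)) {
    d0 <- ds[[i]]
    d1 <- aset$decompositions[[i]]
    expect_identical(d1$eigenvalues, d0$eigenvalues)
    r0 <- d0$time_courses %*% (d0$singvals * t(d0$ecs))
    r1 <- d1$time_courses %*% (d1$singvals * t(d1$ecs))
    expect_lt(max(abs(r0 - r1)), 1e-10)
  }
  expect_true(all(aset$flips %in% c(-1L, 1L)))
})
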