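# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Harmonic pulse waveform
#'
#' Smooth 1-period-per-`1/freq` pulse train built from the first few
#' harmonics of the task frequency: `sum_m w_m cos(2 pi m freq t)`. The
#' default weights `(1, 0.6, sqrt(0.68))` give one dominant maximum per
#' cycle and a dominant fundamental in the magnitude spectrum, and
#' satisfy `w3^2 = (w1^2 + w2^2)/2`, so copies shifted by a third of a
#' period are exactly orthogonal over an integer number of cycles.
#'
#' @param t time points in seconds.
#' @param freq fundamental frequency in Hz.
#' @param weights harmonic weights (length = number of harmonics).
#' @return numeric vector of waveform values (zero mean over full cycles).
#' @export
harmonic_pulse <- function(t, freq, weights = c(1, 0.6, sqrt(0.68))) {
  out <- numeric(length(t))
  for (m in seq_along(weights))
    out <- out + weights[m] * cos(2 * pi * m * freq * t)
  out
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

# Gram-Schmidt on rows, preserving the first row's direction.
orthonormalize_rows <- function(m) {
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    if (i > 1)
      for (j in seq_len(i - 1)) v <- v - sum(v * m[j, ]) * m[j, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stopf("loading rows are linearly dependent")
    m[i, ] <- v / nv
  }
  m
}

#' Stock grasp-configuration loading patterns
#'
#' `default_loadings()` encodes the qualitative structure of the observed
#' expression patterns: component 1 opposes thumb cross/palm arch
#' (positive) to the finger PIP bends (negative); component 2 opposes the
#' finger MCP/PIP bends (positive) to the thumb bend sensors (negative);
#' component 3 is a low-amplitude mixed pattern over abduction and
#' pressure sensors. Rows are orthonormalized (Gram-Schmidt, first row
#' kept), which clean parameter recovery requires; a vector orthogonal
#' to component 1 cannot also be strongly negative on every thumb
#' channel, so component 2's thumb-cross/palm-arch entries are left
#' where orthogonalization puts them (near zero). `module_loadings()`
#' instead uses disjoint channel groups (thumb+palm arch, finger MCP,
#' finger PIP), the planted three-module structure of the joint network.
#'
#' @param layout a [sensor_layout()].
#' @return a 3 x 19 matrix with unit-norm orthogonal rows, columns named
#'   by `layout$relevant19`.
#' @export
default_loadings <- function(layout = default_layout()) {
  ch <- layout$relevant19
  L <- matrix(0, 3, length(ch), dimnames = list(NULL, ch))
  L[1, c("Tcross", "PArch")] <- c(0.62, 0.50)
  L[1, c("MCP_T", "PIP_T")] <- c(0.18, 0.12)
  L[1, c("PIP_I", "PIP_M", "PIP_R", "PIP_L")] <- -0.28
  L[1, c("MCP_I", "MCP_M", "MCP_R", "MCP_L")] <- -0.06
  L[1, c("A4", "P1")] <- c(0.10, -0.12)
  L[2, c("MCP_I", "MCP_M", "MCP_R", "MCP_L")] <- 0.40
  L[2, c("PIP_I", "PIP_M", "PIP_R", "PIP_L")] <- 0.22
  L[2, c("MCP_T", "PIP_T", "Tcross", "PArch")] <- c(-0.22, -0.15, -0.18, -0.10)
  L[2, "A1"] <- -0.08
  L[3, c("A1", "A2", "A3", "A4")] <- c(0.35, 0.25, -0.20, 0.30)
  L[3, c("P1", "P2", "P3")] <- c(-0.35, 0.30, -0.25)
  L[3, c("MCP_M", "PIP_R", "MCP_T")] <- c(0.20, -0.15, 0.25)
  orthonormalize_rows(normalize_rows(L))
}

#' @rdname default_loadings
#' @export
module_loadings <- function(layout = default_layout()) {
  ch <- layout$relevant19
  L <- matrix(0, 3, length(ch), dimnames = list(NULL, ch))
  L[1, c("MCP_T", "PIP_T", "PArch", "Tcross")] <- 0.5
  L[2, c("MCP_I", "MCP_M", "MCP_R", "MCP_L")] <- 0.5
  L[3, c("PIP_I", "PIP_M", "PIP_R", "PIP_L")] <- 0.5
  L
}

#' Specification of a synthetic glove cohort
#'
#' Describes the latent structure the generator emits: `n_components`
#' grasp-configuration components sharing one per-run task frequency
#' (jittered around `base_freq`), each a harmonic pulse delayed by
#' `delays_s` and expressed over the 19 analysis channels through a row
#' of `loadings`, scaled by strictly decreasing `amplitudes`, plus white
#' noise. Per-run loading jitter models within-subject variability.
#'
#' @param n_components number of latent components (default 3).
#' @param base_freq task frequency in Hz (instructed pace, default 1.0).
#' @param freq_jitter_sd per-run frequency jitter SD in Hz.
#' @param loadings `n_components x 19` matrix of unit-norm sensor
#'   patterns (default [default_loadings()]).
#' @param delays_s per-component phase delays in seconds, all in
#'   \[0, 1): defaults to thirds of the 1-s cycle.
#' @param amplitudes per-component scales, strictly decreasing.
#' @param noise_sd additive white-noise SD, in latent signal units
#'   (waveform SD is about 1.2 at the default weights).
#' @param loading_jitter_sd per-run perturbation SD of the loading rows.
#' @param harmonics waveform harmonic weights, see [harmonic_pulse()].
#' @param n_runs,n_subjects,hand cohort layout (study protocol: 6 runs,
#'   22 subjects per hand).
#' @param n_frames,rate frames per emitted run and sampling rate.
#' @param seed integer seed; identical seed gives identical output.
#' @param layout a [sensor_layout()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_components = 3, base_freq = 1.0,
                           freq_jitter_sd = 0.02,
                           loadings = default_loadings(layout),
                           delays_s = c(0, 1, 2)[seq_len(n_components)] / 3,
                           amplitudes = c(1, 0.6, 0.35)[seq_len(n_components)],
                           noise_sd = 0.03, loading_jitter_sd = 0.03,
                           harmonics = c(1, 0.6, sqrt(0.68)),
                           n_runs = 6, n_subjects = 22, hand = "right",
                           n_frames = 800, rate = 50, seed = 1L,
                           layout = default_layout()) {
  loadings <- as.matrix(loadings)[seq_len(n_components), , drop = FALSE]
  if (ncol(loadings) != length(layout$relevant19))
    stopf("loadings must have %d columns", length(layout$relevant19))
  norms <- sqrt(rowSums(loadings^2))
  if (any(abs(norms - 1) > 1e-6))
    stopf("each loading row must have unit Euclidean norm")
  if (length(delays_s) != n_components || any(delays_s < 0 | delays_s >= 1))
    stopf("delays_s must have one entry per component, all in [0, 1) s")
  if (length(amplitudes) != n_components || any(diff(amplitudes) >= 0))
    stopf("amplitudes must be strictly decreasing")
  if (noise_sd < 0 || freq_jitter_sd < 0 || loading_jitter_sd < 0)
    stopf("noise/jitter SDs must be non-negative")
  structure(list(n_components = n_components, base_freq = base_freq,
                 freq_jitter_sd = freq_jitter_sd, loadings = loadings,
                 delays_s = delays_s, amplitudes = amplitudes,
                 noise_sd = noise_sd, loading_jitter_sd = loading_jitter_sd,
                 harmonics = harmonics, n_runs = n_runs,
                 n_subjects = n_subjects,
                 hand = match.arg(hand, c("left", "right")),
                 n_frames = n_frames, rate = rate, seed = as.integer(seed),
                 layout = layout),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec> %d components @ %.2f Hz, ",
                     "delays (%s) s, %d subjects x %d runs (%s hand), seed %d\n"),
              x$n_components, x$base_freq,
              paste(signif(x$delays_s, 3), collapse = ", "),
              x$n_subjects, x$n_runs, x$hand, x$seed))
  invisible(x)
}

#' Simulate a cohort of glove runs with known ground truth
#'
#' Each emitted run is `n_frames` x 19 channels at `rate` Hz: the channel
#' signal is `sum_k amplitude_k * s_k(t - delay_k) * loading_k + noise`,
#' with `s_k` the harmonic pulse at the run's jittered frequency, affinely
#' rescaled into the calibrated \[0, 1000\] range (offset 500, gain set by
#' the run's maximum excursion; the affine map leaves the PCA structure
#' untouched). Sign indeterminacy needs no explicit modelling: the signs
#' a per-run PCA attaches to its components are already arbitrary.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `runs` (list of [sensor_run()]) and `truth`
#'   (class `ground_truth`: per-run realized frequency, delays in s and
#'   frames, loadings, gain/offset of the amplitude map).
#' @export
simulate_runs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    tgrid <- (seq_len(spec$n_frames) - 1) / spec$rate
    runs <- list()
    truth <- list()
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%02d", s)
      for (r in seq_len(spec$n_runs)) {
        f <- spec$base_freq + rnorm(1, 0, spec$freq_jitter_sd)
        L <- spec$loadings
        if (spec$loading_jitter_sd > 0) {
          L <- L + matrix(rnorm(length(L), 0, spec$loading_jitter_sd),
                          nrow(L), ncol(L))
          L <- normalize_rows(L)
        }
        S <- sapply(seq_len(spec$n_components), function(k) {
          w <- harmonic_pulse(tgrid - spec$delays_s[k], f, spec$harmonics)
          w - mean(w)
        })
        X <- S %*% (spec$amplitudes * L)
        if (spec$noise_sd > 0)
          X <- X + matrix(rnorm(length(X), 0, spec$noise_sd), nrow(X), ncol(X))
        gain <- 400 / max(abs(X))
        data <- 500 + gain * X
        colnames(data) <- spec$layout$relevant19
        runs[[length(runs) + 1L]] <-
          sensor_run(data, rate = spec$rate, subject_id = sid,
                     hand = spec$hand, run_index = r, layout = spec$layout)
        truth[[length(truth) + 1L]] <-
          list(subject_id = sid, run_index = r, freq = f,
               delays_s = spec$delays_s,
               delays_frames = spec$delays_s * spec$rate,
               loadings = L, amplitudes = spec$amplitudes,
               gain = gain, offset = 500, noise_sd = spec$noise_sd)
      }
    }
    list(runs = runs, truth = structure(truth, class = "ground_truth"))
  })
}

#' Simulate a cyclic fingertip trajectory series
#'
#' Each of the five fingertips traces a closed circular loop in 3D at
#' `freq` Hz with its own radius, superposed on a static 23-point hand
#' model, plus isotropic Gaussian noise. The loop planes are oriented so
#' that the thumb tip's distance from the hand centroid has exactly one
#' maximum per cycle, which the trajectory segmentation relies on.
#'
#' @param freq cycle frequency in Hz.
#' @param radii_cm per-tip loop radius in cm (scalar recycled to 5).
#' @param n_frames number of frames to emit.
#' @param rate sampling frequency in Hz (3D mode default 36.97).
#' @param noise_mm isotropic coordinate noise SD in mm.
#' @param seed integer seed.
#' @param hand,subject_id,run_index metadata for the emitted series.
#' @return a [hand_point_series()].
#' @export
simulate_trajectory <- function(freq, radii_cm = 2, n_frames = 370,
                                rate = 36.97, noise_mm = 0, seed = 1L,
                                hand = "right", subject_id = "S10",
                                run_index = 1L) {
  if (freq <= 0) stopf("freq must be positive")
  if (rate <= 2 * freq)
    stopf("sampling rate %g Hz aliases a %g Hz loop (need rate > 2*freq)", rate, freq)
  radii_mm <- rep_len(radii_cm, 5) * 10
  tips <- paste0("TIP_", c("T", "I", "M", "R", "L"))
  statics <- c(paste0("MCPJ_", c("T", "I", "M", "R", "L")),
               paste0("PIPJ_", c("T", "I", "M", "R", "L")),
               paste0("DIPJ_", c("I", "M", "R", "L")),
               "WRIST_U", "WRIST_R", "PALM_C", "PALM_D")
  centers <- rbind(TIP_T = c(60, -30, 15), TIP_I = c(85, 10, 5),
                   TIP_M = c(90, 30, 5), TIP_R = c(85, 50, 5),
                   TIP_L = c(70, 65, 10))
  # static skeleton points: a rough open hand around the origin
  static_xyz <- cbind(x = c(20, 35, 38, 35, 28, 40, 60, 63, 60, 50,
                            75, 78, 75, 62, -20, -15, 10, 25),
                      y = c(-20, 5, 20, 35, 48, -25, 8, 25, 42, 55,
                            9, 27, 46, 60, -5, 25, 10, 30),
                      z = c(12, 2, 0, 2, 6, 14, 3, 1, 3, 8,
                            4, 2, 4, 9, 0, 0, 0, 2))
  rownames(static_xyz) <- statics
  with_seed(seed, {
    tgrid <- (seq_len(n_frames) - 1) / rate
    # thumb phase 0.5 keeps its extension maxima off the window edges
    phases <- c(0.5, 0.15, 0.3, 0.45, 0.6) * 2 * pi
    coords <- array(0, dim = c(n_frames, 23, 3),
                    dimnames = list(NULL, c(tips, statics), c("x", "y", "z")))
    centroid0 <- colMeans(rbind(centers, static_xyz))
    for (i in seq_along(tips)) {
      # u points away from the hand centroid so tip-centroid distance
      # oscillates once per cycle
      u <- centers[i, ] - centroid0
      u <- u / sqrt(sum(u^2))
      a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      v <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
             u[1] * a[2] - u[2] * a[1])
      v <- v / sqrt(sum(v^2))
      theta <- 2 * pi * freq * tgrid + phases[i]
      pos <- outer(cos(theta), radii_mm[i] * u) + outer(sin(theta), radii_mm[i] * v)
      coords[, tips[i], ] <- sweep(pos, 2, centers[i, ], "+")
    }
    for (p in statics)
      coords[, p, ] <- matrix(static_xyz[p, ], n_frames, 3, byrow = TRUE)
    if (noise_mm > 0)
      coords <- coords + array(rnorm(length(coords), 0, noise_mm), dim = dim(coords))
    hand_point_series(coords, rate = rate, tip_points = tips, hand = hand,
                      subject_id = subject_id, run_index = run_index)
  })
}
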