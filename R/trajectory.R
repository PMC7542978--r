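euclid_path_length <- function(frames) {
  if (nrow(frames) < 2) return(0)
  sum(sqrt(rowSums(diff(frames)^2)))
}

# Thumb-extension scalar: per-frame distance of the thumb tip from the
# time-mean centroid of the full 23-point model (default), or a single
# coordinate axis of the thumb tip.
thumb_extension <- function(series, reference = c("centroid", "axis"), axis = 1) {
  reference <- match.arg(reference)
  thumb <- series$coords[, series$tip_points[1], ]
  if (reference == "axis") return(thumb[, axis])
  centroid <- apply(series$coords, 3, mean)  # time-mean centroid, xyz
  sqrt(rowSums(sweep(thumb, 2, centroid)^2))
}

#' Segment a point series into per-manipulation trajectories
#'
#' One trajectory spans the frames between consecutive maximal
#' extensions of the thumb. The extension scalar is, by default, the
#' thumb tip's distance from the time-mean centroid of the 23-point
#' hand model (a single coordinate axis is available as an
#' alternative); its peaks cut the series, and each inter-peak interval
#' yields one trajectory per fingertip.
#'
#' @param series a [hand_point_series()]; the first `tip_points` entry
#'   is taken as the thumb tip.
#' @param reference `"centroid"` (default) or `"axis"` extension scalar.
#' @param axis coordinate index when `reference = "axis"`.
#' @param min_sep_s minimum peak separation in seconds.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   extension scalar's range.
#' @return named list (one entry per fingertip) of lists of
#'   `trajectory` objects with fields `tip`, `frames` (n x 3, mm),
#'   `duration_s`, `path_length_mm`, `speed_cm_s`.
#' @export
segment_trajectories <- function(series, reference = c("centroid", "axis"),
                                 axis = 1, min_sep_s = 0.4,
                                 prominence_frac = 0.3) {
  stopifnot(inherits(series, "hand_point_series"))
  ext <- thumb_extension(series, reference, axis)
  if (diff(range(ext)) == 0)
    stopf("stationary thumb: no extension peaks to segment at")
  peaks <- find_peaks(ext, min_sep = min_sep_s * series$rate,
                      min_prominence = prominence_frac * diff(range(ext)))
  if (length(peaks) < 2)
    stopf("fewer than 2 thumb-extension maxima: cannot segment")
  out <- lapply(series$tip_points, function(tip) {
    xyz <- series$coords[, tip, ]
    lapply(seq_len(length(peaks) - 1), function(i) {
      idx <- seq.int(peaks[i], peaks[i + 1])
      frames <- xyz[idx, , drop = FALSE]
      duration <- (length(idx) - 1) / series$rate
      plen <- euclid_path_length(frames)
      structure(list(tip = tip, frames = frames, duration_s = duration,
                     path_length_mm = plen,
                     speed_cm_s = (plen / 10) / duration),
                class = "trajectory")
    })
  })
  names(out) <- series$tip_points
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %.0f mm in %.2f s (%.1f cm/s)\n",
              x$tip, x$path_length_mm, x$duration_s, x$speed_cm_s))
  invisible(x)
}

# Resample a polyline to n points uniform in cumulative arc length;
# endpoints preserved.
resample_arclength <- function(frames, n = 100) {
  d <- sqrt(rowSums(diff(frames)^2))
  s <- c(0, cumsum(d))
  if (s[length(s)] == 0)
    return(matrix(frames[1, ], n, 3, byrow = TRUE,
                  dimnames = list(NULL, colnames(frames))))
  keep <- c(TRUE, d > 0)  # drop duplicated points so s is strictly increasing
  s <- s[keep]
  frames <- frames[keep, , drop = FALSE]
  grid <- seq(0, s[length(s)], length.out = n)
  apply(frames, 2, function(col) approx(s, col, xout = grid)$y)
}

#' Summary statistics and mean trajectory for one fingertip
#'
#' Per-trajectory repetition frequency (1/duration) and speed with
#' medians and interquartile ranges; each trajectory resampled to 100
#' points uniformly in cumulative arc length (so speed variation along
#' the path does not distort the mean shape); the pointwise mean
#' trajectory; and a 95% error ellipsoid per resampled point from the
#' 3 x 3 covariance across trajectories at the chi-square(3) quantile.
#'
#' @param trajs list of `trajectory` objects for one tip (>= 3).
#' @param n_points resampled length (study value 100).
#' @param conf ellipsoid confidence level.
#' @return an object of class `trajectory_summary`: `n`, `median_freq`,
#'   `iqr_freq`, `median_speed`, `mean_traj` (n_points x 3),
#'   `covariances` (3 x 3 x n_points), `ellipsoid_scale`
#'   (sqrt of the chi-square quantile), `degenerate` (per-point flag
#'   for rank-deficient covariance).
#' @export
summarize_trajectories <- function(trajs, n_points = 100, conf = 0.95) {
  if (length(trajs) < 3) stopf("need >= 3 trajectories, got %d", length(trajs))
  freqs <- vapply(trajs, function(t) 1 / t$duration_s, 0)
  speeds <- vapply(trajs, function(t) t$speed_cm_s, 0)
  res <- array(NA_real_, dim = c(n_points, 3, length(trajs)))
  for (i in seq_along(trajs))
    res[, , i] <- resample_arclength(trajs[[i]]$frames, n_points)
  mean_traj <- apply(res, c(1, 2), mean)
  colnames(mean_traj) <- c("x", "y", "z")
  covs <- array(NA_real_, dim = c(3, 3, n_points))
  degenerate <- logical(n_points)
  for (p in seq_len(n_points)) {
    covs[, , p] <- cov(t(res[p, , ]))
    degenerate[p] <- qr(covs[, , p])$rank < 3
  }
  if (any(degenerate))
    warnf("%d of %d resampled points have rank-deficient covariance (ellipsoid collapses)",
          sum(degenerate), n_points)
  structure(list(n = length(trajs), tip = trajs[[1]]$tip,
                 median_freq = median(freqs),
                 iqr_freq = unname(quantile(freqs, c(0.25, 0.75))),
                 median_speed = median(speeds),
                 mean_traj = mean_traj, covariances = covs,
                 ellipsoid_scale = sqrt(qchisq(conf, df = 3)),
                 degenerate = degenerate),
            class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("<trajectory_summary> %s: %d trajectories, median %.2f Hz (IQR %.2f-%.2f), median speed %.1f cm/s\n",
              x$tip, x$n, x$median_freq, x$iqr_freq[1], x$iqr_freq[2],
              x$median_speed))
  invisible(x)
}
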