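#' Per-run principal component decomposition
#'
#' Applies PCA to the residual matrix of one analysis-ready run: the
#' frames x channels data minus the per-channel mean (no variance
#' scaling, so expression coefficients stay in calibrated amplitude
#' units). The singular value decomposition yields, for each component,
#' a sensor expression pattern (EC), an orthonormal time course and an
#' eigenvalue; the eigenvalue fraction is the share of variance the
#' component describes.
#'
#' @param run a [sensor_run()], typically 800 frames x 19 channels.
#' @return an object of class `decomposition` with fields `ecs`
#'   (channels x K, right singular vectors), `time_courses` (frames x K,
#'   left singular vectors), `singvals`, `eigenvalues` (descending),
#'   `var_fraction`, `center`, and `run_ref`.
#' @export
decompose_run <- function(run) {
  stopifnot(inherits(run, "sensor_run"))
  X <- run$data
  if (nrow(X) < ncol(X))
    stopf("run has fewer frames (%d) than channels (%d): rank-deficient in time",
          nrow(X), ncol(X))
  vars <- apply(X, 2, var)
  if (any(vars == 0))
    warnf("zero-variance channel(s) retained: %s",
          paste(colnames(X)[vars == 0], collapse = ", "))
  center <- colMeans(X)
  R <- sweep(X, 2, center)
  sv <- svd(R)
  eig <- sv$d^2 / (nrow(X) - 1)
  structure(list(ecs = `rownames<-`(sv$v, colnames(X)),
                 time_courses = sv$u,
                 singvals = sv$d,
                 eigenvalues = eig,
                 var_fraction = sv$d^2 / sum(sv$d^2),
                 center = center,
                 rate = run$rate,
                 run_ref = list(subject_id = run$subject_id, hand = run$hand,
                                run_index = run$run_index)),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %s %s run %d: %d channels, top-3 variance %.1f%%\n",
              x$run_ref$subject_id, x$run_ref$hand, x$run_ref$run_index,
              nrow(x$ecs), 100 * sum(x$var_fraction[1:min(3, length(x$var_fraction))])))
  invisible(x)
}

# Reconstruct the residual (centered) matrix from the decomposition.
reconstruct_residual <- function(d) {
  d$time_courses %*% (d$singvals * t(d$ecs))
}

#' Guttman-Kaiser count of salient components
#'
#' Number of eigenvalues strictly exceeding the mean eigenvalue of the
#' run - the scale-free generalization of the "eigenvalue > 1" rule to a
#' covariance-based PCA.
#'
#' @param d a [decompose_run()] result, or a numeric eigenvalue vector.
#' @return integer count of salient components.
#' @export
guttman_kaiser <- function(d) {
  eig <- if (inherits(d, "decomposition")) d$eigenvalues else as.numeric(d)
  sum(eig > mean(eig))
}

# ---- sign alignment ----------------------------------------------------

# Signs maximizing sum_{i<j} s_i s_j cor(v_i, v_j) over rows of `vecs`.
# Exact enumeration (first sign fixed +1) for n <= exact_max; otherwise
# greedy anchor-to-first followed by sweeps to a fixed point. Ties keep
# the current (+1) sign, so mutually orthogonal inputs return identity.
sign_align <- function(vecs, exact_max = 12) {
  n <- nrow(vecs)
  if (n == 1) return(1)
  C <- cor(t(vecs))
  diag(C) <- 0
  if (n <= exact_max) {
    best <- rep(1, n)
    best_obj <- sum(C * tcrossprod(best)) / 2
    for (code in seq_len(2^(n - 1) - 1)) {
      s <- c(1, 1 - 2 * as.integer(intToBits(code))[seq_len(n - 1)])
      obj <- sum(C * tcrossprod(s)) / 2
      if (obj > best_obj + 1e-12) {
        best <- s
        best_obj <- obj
      }
    }
    best
  } else {
    s <- sign(C[, 1])
    s[s == 0] <- 1
    s[1] <- 1
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        field <- sum(C[i, ] * s) - C[i, i] * s[i]
        si <- if (field > 0) 1 else if (field < 0) -1 else s[i]
        if (si != s[i]) {
          s[i] <- si
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    s
  }
}

#' Align component signs within a subject
#'
#' PCA determines components only up to sign. For the runs of one
#' subject and one component index, returns per-run signs that maximize
#' the summed pairwise Pearson correlation among the signed EC vectors
#' (exact over all sign patterns for up to 12 runs; deterministic greedy
#' sweep beyond). Ties keep +1, so orthogonal ECs are left untouched.
#'
#' @param ds list of [decompose_run()] results from one subject and hand.
#' @param component component index (column of `ecs`).
#' @return integer vector of signs, one per run.
#' @export
align_within_subject <- function(ds, component) {
  stopifnot(length(ds) >= 1)
  if (length(ds) == 1) return(1L)
  ecs <- t(sapply(ds, function(d) d$ecs[, component]))
  as.integer(sign_align(ecs))
}

#' Align component signs across subjects
#'
#' Second alignment stage: one sign per subject (applied to all its
#' runs) maximizing the summed pairwise correlation of the subject-mean
#' EC vectors, followed by a canonical global sign chosen so the summed
#' loading over the thumb cross and finger MCP/PIP channels is positive
#' (positive then means increased bending of those sensors).
#'
#' @param subject_means matrix, one row per subject: the mean aligned EC
#'   vector of that subject for one component; columns named by channel.
#' @param canonical_channels channels whose summed loading fixes the
#'   global sign.
#' @return integer vector of per-subject signs, canonical flip included.
#' @export
align_across_subjects <- function(subject_means,
                                  canonical_channels = canonical_sign_channels()) {
  subject_means <- as.matrix(subject_means)
  s <- if (nrow(subject_means) == 1) 1 else sign_align(subject_means)
  aligned_mean <- colMeans(subject_means * s)
  canon <- intersect(canonical_channels, colnames(subject_means))
  g <- sum(aligned_mean[canon])
  as.integer(s * if (g < 0) -1 else 1)
}

# Apply per-component signs jointly to EC columns and time courses.
apply_flips <- function(d, flips) {
  k <- length(flips)
  d$ecs[, seq_len(k)] <- sweep(d$ecs[, seq_len(k), drop = FALSE], 2, flips, "*")
  d$time_courses[, seq_len(k)] <-
    sweep(d$time_courses[, seq_len(k), drop = FALSE], 2, flips, "*")
  d
}

#' Two-stage sign alignment of a cohort of decompositions
#'
#' Runs [align_within_subject()] per subject and component, then
#' [align_across_subjects()] on the subject-mean ECs, and applies the
#' combined signs. Flipping an EC column together with its time course
#' leaves eigenvalues and the reconstruction unchanged.
#'
#' @param ds list of [decompose_run()] results (one hand).
#' @param n_components number of leading components to align (default 3).
#' @param canonical_channels see [align_across_subjects()].
#' @return an object of class `aligned_set`: `decompositions` (flipped),
#'   `flips` (runs x components matrix of applied signs), and the run
#'   tags `subject_id`, `run_index`.
#' @export
align_cohort <- function(ds, n_components = 3,
                         canonical_channels = canonical_sign_channels()) {
  subjects <- vapply(ds, function(d) d$run_ref$subject_id, "")
  flips <- matrix(1L, length(ds), n_components)
  for (k in seq_len(n_components)) {
    # stage 1: within subject
    for (sid in unique(subjects)) {
      idx <- which(subjects == sid)
      flips[idx, k] <- align_within_subject(ds[idx], k)
    }
    # stage 2: across subjects, on subject means of stage-1-aligned ECs
    usub <- unique(subjects)
    means <- t(sapply(usub, function(sid) {
      idx <- which(subjects == sid)
      ecs <- sapply(idx, function(i) ds[[i]]$ecs[, k] * flips[i, k])
      rowMeans(ecs)
    }))
    colnames(means) <- rownames(ds[[1]]$ecs)
    s2 <- align_across_subjects(means, canonical_channels)
    for (j in seq_along(usub))
      flips[subjects == usub[j], k] <- flips[subjects == usub[j], k] * s2[j]
  }
  flipped <- lapply(seq_along(ds), function(i) apply_flips(ds[[i]], flips[i, ]))
  structure(list(decompositions = flipped, flips = flips,
                 subject_id = subjects,
                 run_index = vapply(ds, function(d) d$run_ref$run_index, 1L),
                 hand = ds[[1]]$run_ref$hand),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d runs, %d subjects, %d aligned components (%s hand)\n",
              length(x$decompositions), length(unique(x$subject_id)),
              ncol(x$flips), x$hand))
  invisible(x)
}

#' Stack aligned expression patterns into tagged items
#'
#' Flattens an [align_cohort()] result into the item matrix the cluster
#' taxonomy consumes: one row per (run, component) pair.
#'
#' @param aset an `aligned_set`.
#' @param n_components leading components to include.
#' @return list with `ecs` (items x channels matrix), and parallel tag
#'   vectors `component`, `subject_id`, `run_index`.
#' @export
aligned_items <- function(aset, n_components = ncol(aset$flips)) {
  stopifnot(inherits(aset, "aligned_set"))
  rows <- list()
  comp <- integer()
  subj <- character()
  runi <- integer()
  for (i in seq_along(aset$decompositions)) {
    d <- aset$decompositions[[i]]
    for (k in seq_len(n_components)) {
      rows[[length(rows) + 1L]] <- d$ecs[, k]
      comp <- c(comp, k)
      subj <- c(subj, aset$subject_id[i])
      runi <- c(runi, aset$run_index[i])
    }
  }
  list(ecs = do.call(rbind, rows), component = comp,
       subject_id = subj, run_index = runi)
}
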