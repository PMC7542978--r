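#' A single data-glove run
#'
#' One acquisition ("run") of consecutive cuboid manipulations: a frames x
#' channels matrix of calibrated sensor amplitudes in \[0, 1000\], sampled
#' at `rate` Hz, with subject/hand/run metadata. Raw runs have 1000 frames
#' at 50 Hz; analysis-ready runs are trimmed to their last 800 frames
#' (16 s) with [trim_run()].
#'
#' @param data numeric matrix, frames in rows, channels in columns; column
#'   names must be channel labels known to `layout`.
#' @param rate sampling frequency in Hz.
#' @param subject_id subject identifier.
#' @param hand `"left"` or `"right"`.
#' @param run_index run number within the session (1..6 in the study
#'   protocol; not enforced).
#' @param layout a [sensor_layout()].
#' @return an object of class `sensor_run`.
#' @export
sensor_run <- function(data, rate = 50, subject_id = "S01", hand = "right",
                       run_index = 1L, layout = default_layout()) {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    stopf("run data needs channel labels as column names")
  unknown <- setdiff(colnames(data), layout$labels)
  if (length(unknown))
    stopf("unknown channel(s): %s", paste(unknown, collapse = ", "))
  if (anyDuplicated(colnames(data)))
    stopf("duplicate channel(s): %s",
          paste(unique(colnames(data)[duplicated(colnames(data))]), collapse = ", "))
  if (!is.numeric(data) || anyNA(data))
    stopf("run data must be numeric and complete")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1000)
    stopf("amplitude out of calibrated range [0, 1000]: observed [%g, %g]",
          rng[1], rng[2])
  hand <- match.arg(hand, c("left", "right"))
  structure(list(data = data, rate = rate, subject_id = subject_id,
                 hand = hand, run_index = as.integer(run_index),
                 layout = layout),
            class = "sensor_run")
}

#' @export
print.sensor_run <- function(x, ...) {
  cat(sprintf("<sensor_run> %s %s hand run %d: %d frames x %d channels @ %g Hz\n",
              x$subject_id, x$hand, x$run_index,
              nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' @export
dim.sensor_run <- function(x) dim(x$data)

#' Restrict a run to its final frames
#'
#' The first part of each 20-s run contains irregularities while the
#' subject locks onto the instructed pace; analysis uses only the last
#' 800 frames (16 s at 50 Hz).
#'
#' @param run a [sensor_run()].
#' @param keep_last number of trailing frames to keep (default 800).
#' @return the run restricted to its final `keep_last` frames.
#' @export
trim_run <- function(run, keep_last = 800) {
  stopifnot(inherits(run, "sensor_run"))
  n <- nrow(run$data)
  if (keep_last > n)
    stopf("cannot keep last %d frames of a %d-frame run", keep_last, n)
  run$data <- run$data[seq.int(n - keep_last + 1L, n), , drop = FALSE]
  run
}

#' Select and reorder channels of a run
#'
#' @param run a [sensor_run()].
#' @param subset ordered character vector of channel labels, e.g.
#'   `default_layout()$relevant19` or `default_layout()$graph12`.
#' @return the run restricted to `subset`, in that order.
#' @export
select_channels <- function(run, subset) {
  stopifnot(inherits(run, "sensor_run"))
  missing <- setdiff(subset, colnames(run$data))
  if (length(missing))
    stopf("channel(s) not present in run: %s", paste(missing, collapse = ", "))
  run$data <- run$data[, subset, drop = FALSE]
  run
}

# ---- run files: UTF-8 TSV, '#key=value' metadata lines, header row with
# a 1-based 'frame' column followed by channel labels --------------------

read_meta_lines <- function(path) {
  lines <- readLines(path, n = 64L, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  meta
}

#' Write a run to a tab-separated file
#'
#' Dialect: UTF-8 TSV; metadata (`subject`, `hand`, `run`, `rate`) as
#' `#key=value` comment lines; one header row (`frame` plus channel
#' labels); one row per frame with an explicit 1-based frame index.
#'
#' @param run a [sensor_run()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "sensor_run"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#subject=%s", run$subject_id),
               sprintf("#hand=%s", run$hand),
               sprintf("#run=%d", run$run_index),
               sprintf("#rate=%.10g", run$rate)), con)
  df <- data.frame(frame = seq_len(nrow(run$data)), run$data,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run from a tab-separated file
#'
#' Columns may be permuted relative to the canonical layout order; the
#' reader normalizes them. Amplitudes are validated against the
#' calibrated range \[0, 1000\].
#'
#' @param path file written by [write_run()] (or equivalent).
#' @param layout a [sensor_layout()] the channel labels must belong to.
#' @return a [sensor_run()].
#' @export
read_run <- function(path, layout = default_layout()) {
  meta <- read_meta_lines(path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   colClasses = "numeric")
  if (nrow(df) < 1) stopf("%s: no data rows", path)
  chan <- names(df)[names(df) != "frame"]  # setdiff would hide duplicates
  unknown <- setdiff(chan, layout$labels)
  if (length(unknown))
    stopf("%s: unknown channel(s): %s", path, paste(unknown, collapse = ", "))
  if (anyDuplicated(chan))
    stopf("%s: duplicate channel(s): %s", path,
          paste(unique(chan[duplicated(chan)]), collapse = ", "))
  mat <- as.matrix(df[, chan, drop = FALSE])
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stopf("%s: non-numeric cell at row %d, channel %s", path,
          idx[1], chan[idx[2]])
  }
  # normalize to canonical order for the channels present
  mat <- mat[, layout$labels[layout$labels %in% chan], drop = FALSE]
  sensor_run(mat,
             rate = as.numeric(meta$rate %||% 50),
             subject_id = meta$subject %||% "unknown",
             hand = meta$hand %||% "right",
             run_index = as.integer(meta$run %||% 1L),
             layout = layout)
}

# ---- 3D hand-model point series ----------------------------------------

#' A 3D hand-model point series
#'
#' Per-frame x,y,z positions (mm) of the 23 standardized hand-model
#' points exported from the vendor's 3D acquisition mode, with the five
#' distal-phalanx end points flagged as fingertips.
#'
#' @param coords numeric array `frames x 23 x 3` (or a frames x 69 matrix
#'   with columns `<point>_x,<point>_y,<point>_z`), dimnames carrying
#'   point names.
#' @param rate sampling frequency in Hz (3D mode default 36.97).
#' @param tip_points names of the five fingertip points.
#' @param hand,subject_id,run_index acquisition metadata.
#' @return an object of class `hand_point_series`.
#' @export
hand_point_series <- function(coords, rate = 36.97,
                              tip_points = paste0("TIP_", c("T", "I", "M", "R", "L")),
                              hand = "right", subject_id = "S01",
                              run_index = 1L) {
  if (is.matrix(coords)) {
    if (ncol(coords) != 69) stopf("expected 69 coordinate columns, got %d",
                                  ncol(coords))
    nms <- unique(sub("_[xyz]$", "", colnames(coords)))
    coords <- array(coords[, paste0(rep(nms, each = 3), "_", c("x", "y", "z"))],
                    dim = c(nrow(coords), 3, length(nms)))
    coords <- aperm(coords, c(1, 3, 2))
    dimnames(coords) <- list(NULL, nms, c("x", "y", "z"))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != 23) stopf("expected 23 hand points, got %d", dim(coords)[2])
  if (!all(is.finite(coords))) stopf("non-finite coordinates")
  pts <- dimnames(coords)[[2]]
  if (length(tip_points) != 5 || !all(tip_points %in% pts))
    stopf("tip_points must name 5 of the 23 points")
  structure(list(coords = coords, rate = rate, tip_points = tip_points,
                 hand = match.arg(hand, c("left", "right")),
                 subject_id = subject_id, run_index = as.integer(run_index)),
            class = "hand_point_series")
}

#' @export
print.hand_point_series <- function(x, ...) {
  cat(sprintf("<hand_point_series> %s %s hand run %d: %d frames x 23 points @ %g Hz\n",
              x$subject_id, x$hand, x$run_index, dim(x$coords)[1], x$rate))
  invisible(x)
}

#' Write a hand-point series to TSV
#'
#' Columns: `frame`, then `<point>_x,<point>_y,<point>_z` for each of the
#' 23 points, in mm. Metadata in `#key=value` lines, including the
#' fingertip point names.
#'
#' @param series a [hand_point_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_points <- function(series, path) {
  stopifnot(inherits(series, "hand_point_series"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#subject=%s", series$subject_id),
               sprintf("#hand=%s", series$hand),
               sprintf("#run=%d", series$run_index),
               sprintf("#rate=%.10g", series$rate),
               sprintf("#tips=%s", paste(series$tip_points, collapse = ","))),
             con)
  pts <- dimnames(series$coords)[[2]]
  flat <- matrix(aperm(series$coords, c(1, 3, 2)), nrow = dim(series$coords)[1])
  colnames(flat) <- paste0(rep(pts, each = 3), "_", c("x", "y", "z"))
  df <- data.frame(frame = seq_len(nrow(flat)), flat, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hand-point series from TSV
#'
#' @param path file written by [write_points()] (or equivalent export).
#' @return a [hand_point_series()].
#' @export
read_points <- function(path) {
  meta <- read_meta_lines(path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   colClasses = "numeric")
  cn <- setdiff(names(df), "frame")
  if (length(cn) != 69)
    stopf("%s: expected 69 coordinate columns (23 points x 3), got %d",
          path, length(cn))
  mat <- as.matrix(df[, cn, drop = FALSE])
  tips <- if (!is.null(meta$tips)) strsplit(meta$tips, ",")[[1]] else
    paste0("TIP_", c("T", "I", "M", "R", "L"))
  hand_point_series(mat, rate = as.numeric(meta$rate %||% 36.97),
                    tip_points = tips, hand = meta$hand %||% "right",
                    subject_id = meta$subject %||% "unknown",
                    run_index = as.integer(meta$run %||% 1L))
}
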