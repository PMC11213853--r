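#' Multichannel continuous signal
#'
#' Container for a D-feature by T-frame recording, the object every
#' segmentation operation refers to. Values are stored as a numeric matrix
#' with one row per feature and one column per frame.
#'
#' @param values Numeric matrix, features in rows, frames in columns. A data
#'   frame with frames in rows (the on-disk CSV layout) is transposed.
#' @param frame_rate Acquisition rate in frames per second.
#' @param feature_names Optional character vector of feature identifiers;
#'   defaults to row names or `f1..fD`.
#' @return An object of class `tasc_signal` with elements `values`,
#'   `frame_rate` and `feature_names`.
#' @export
tasc_signal <- function(values, frame_rate = 120, feature_names = NULL) {
  if (is.data.frame(values)) {
    feature_names <- feature_names %||% names(values)
    values <- t(as.matrix(values))
  }
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x frames)")
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("signal must have at least one feature and one frame")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value in feature %d at frame %d", bad[1, 1], bad[1, 2]))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("`frame_rate` must be a positive scalar")
  feature_names <- feature_names %||% rownames(values) %||%
    paste0("f", seq_len(nrow(values)))
  if (length(feature_names) != nrow(values))
    stop("`feature_names` length must equal the number of features")
  rownames(values) <- feature_names
  structure(list(values = unname(values) , frame_rate = frame_rate,
                 feature_names = as.character(feature_names)),
            class = "tasc_signal")
}

#' @export
print.tasc_signal <- function(x, ...) {
  cat(sprintf("<tasc_signal> %d features x %d frames @ %g fps\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' @rdname tasc_signal
#' @param x Object to coerce.
#' @export
as_tasc_signal <- function(x, frame_rate = 120) {
  if (inherits(x, "tasc_signal")) return(x)
  tasc_signal(x, frame_rate = frame_rate)
}

#' @noRd
n_frames <- function(signal) ncol(signal$values)

#' Read a signal from CSV
#'
#' Frames are rows and features are columns, with a header row of feature
#' names -- the layout pose-processing pipelines typically export.
#'
#' @param path CSV file path.
#' @param frame_rate Frames per second of the recording.
#' @return A [tasc_signal()].
#' @export
read_signal_csv <- function(path, frame_rate = 120) {
  df <- read.csv(path, check.names = FALSE)
  tasc_signal(df, frame_rate = frame_rate)
}

#' Write a signal to CSV (frames as rows)
#' @param signal A [tasc_signal()].
#' @param path Output path.
#' @export
write_signal_csv <- function(signal, path) {
  df <- as.data.frame(t(signal$values))
  names(df) <- signal$feature_names
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Min-max normalize each feature to [0, 1]
#'
#' Constant features map to all-zero. Idempotent: normalizing a normalized
#' signal changes nothing.
#'
#' @param signal A [tasc_signal()].
#' @return The normalized [tasc_signal()].
#' @export
normalize_signal <- function(signal) {
  signal <- as_tasc_signal(signal)
  v <- signal$values
  lo <- apply(v, 1, min)
  hi <- apply(v, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant features: (v - lo) is 0 already
  signal$values <- (v - lo) / rng
  signal
}

#' Detect candidate activity periods
#'
#' Frames with enough motion energy to be worth segmenting. Per-frame energy
#' is the sum across features of the absolute first difference; it is
#' smoothed with a zero-phase Butterworth low-pass filter and thresholded at
#' a quantile of the smoothed-energy distribution. Active runs shorter than
#' `min_period_frames` are suppressed.
#'
#' @param signal A normalized [tasc_signal()].
#' @param cutoff_hz Low-pass cutoff in Hz; must lie below the Nyquist rate.
#' @param threshold_quantile Quantile of the smoothed energy used as the
#'   activity threshold (default 0.25, i.e. the quietest quarter of frames is
#'   treated as rest).
#' @param min_period_frames Minimum length of an active run, in frames.
#' @param close_gap_frames Inactive runs shorter than this are absorbed into
#'   the surrounding activity (morphological closing) before short active
#'   runs are culled; bridges the near-zero-derivative instants inside a
#'   smooth movement without smearing its edges.
#' @return A list of class `tasc_activity`: logical `active` (length T),
#'   `threshold_used`, and the `smoothed_energy` vector.
#' @export
detect_activity_periods <- function(signal, cutoff_hz = 1,
                                    threshold_quantile = 0.25,
                                    min_period_frames = 1,
                                    close_gap_frames = 0) {
  signal <- as_tasc_signal(signal)
  T_ <- n_frames(signal)
  if (T_ < 3) stop("signal too short for activity detection (need >= 3 frames)")
  nyq <- signal$frame_rate / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop(sprintf("`cutoff_hz` must lie in (0, %g)", nyq))
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("`threshold_quantile` must lie in (0, 1)")
  d <- abs(signal$values[, -1, drop = FALSE] - signal$values[, -T_, drop = FALSE])
  energy <- c(0, colSums(d))
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  smoothed <- as.numeric(signal::filtfilt(bf, energy))
  # floor keeps a motionless recording fully inactive (smoothed energy 0)
  threshold <- max(unname(quantile(smoothed, threshold_quantile)), 1e-8)
  active <- smoothed >= threshold
  if (close_gap_frames > 0 && any(active)) {
    r <- rle(active)
    inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    r$values[!r$values & r$lengths < close_gap_frames & inner] <- TRUE
    active <- inverse.rle(r)
  }
  if (min_period_frames > 1 && any(active)) {
    r <- rle(active)
    r$values[r$values & r$lengths < min_period_frames] <- FALSE
    active <- inverse.rle(r)
  }
  structure(list(active = active, threshold_used = threshold,
                 smoothed_energy = smoothed),
            class = "tasc_activity")
}

#' Keep segments that lie mostly inside activity periods
#'
#' A segment is valid when the fraction of its frames flagged active is at
#' least `min_fraction` (inclusive). Order is preserved.
#'
#' @param segments Segment data frame (see [new_segments()]).
#' @param mask A `tasc_activity` object or logical vector of length T.
#' @param min_fraction Required active fraction (default 0.9).
#' @return The retained subset of `segments`.
#' @export
filter_valid_segments <- function(segments, mask, min_fraction = 0.9) {
  if (nrow(segments) == 0) return(segments)
  active <- if (inherits(mask, "tasc_activity")) mask$active else as.logical(mask)
  cum <- c(0, cumsum(active))
  inside <- cum[segments$end + 1] - cum[segments$start + 1]
  keep <- inside / (segments$end - segments$start) >= min_fraction
  segments[keep, , drop = FALSE]
}
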