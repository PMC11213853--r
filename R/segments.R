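#' Segment lists
#'
#' Segments are half-open, 0-based frame intervals `[start, end)`, so
#' `length = end - start` and two segments overlap iff
#' `start_a < end_b && start_b < end_a`. They are kept in an ordinary data
#' frame with columns `start`, `end`, `label` (cluster id, `NA` =
#' unassigned), `score`, `tau_w`, `s_w`, `cost`.
#'
#' @param start,end Integer vectors of interval boundaries, `start < end`.
#' @param label Integer cluster ids or `NA`.
#' @param score Selection score in `[0, 1]` or `NA`.
#' @param tau_w,s_w,cost Stored alignment parameters and cost, or `NA`.
#' @return A data frame with one row per segment.
#' @export
new_segments <- function(start, end, label = NA_integer_, score = NA_real_,
                         tau_w = NA_real_, s_w = NA_real_, cost = NA_real_) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = as.integer(label), score = as.numeric(score),
                   tau_w = as.numeric(tau_w), s_w = as.numeric(s_w),
                   cost = as.numeric(cost))
  validate_segments(df)
  df
}

#' Validate a segment data frame
#' @param segments Segment data frame.
#' @param n_frames Optional signal length T; when given, segments must lie in
#'   `[0, T)`.
#' @param require_nonoverlap Additionally require sorted, pairwise
#'   non-overlapping intervals.
#' @return `segments`, invisibly.
#' @export
validate_segments <- function(segments, n_frames = NULL,
                              require_nonoverlap = FALSE) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end") %in% names(segments)))
  if (nrow(segments) == 0) return(invisible(segments))
  if (any(segments$start < 0)) stop("segment start before frame 0")
  if (any(segments$end - segments$start < 2))
    stop("segments must span at least 2 frames")
  if (!is.null(n_frames) && any(segments$end > n_frames))
    stop(sprintf("segment end beyond signal length %d", n_frames))
  if (require_nonoverlap) {
    o <- order(segments$start)
    s <- segments[o, ]
    if (any(s$start[-1] < s$end[-nrow(s)]))
      stop("segments overlap")
  }
  invisible(segments)
}

#' Initial naive segmentation
#'
#' Cuts the recording into fixed windows `[k*stride, k*stride + window)` for
#' every k with `end <= T`. A stride smaller than the window yields
#' overlapping candidates; overlaps are resolved later by the score-based
#' dynamic program.
#'
#' @param signal A [tasc_signal()] (or the frame count T).
#' @param window Window size in frames (>= 2).
#' @param stride Hop between window starts; defaults to `window`
#'   (non-overlapping tiling).
#' @return A segment data frame.
#' @export
naive_segmentation <- function(signal, window, stride = window) {
  T_ <- if (is.numeric(signal)) as.integer(signal) else n_frames(as_tasc_signal(signal))
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 2) stop("`window` must be >= 2")
  if (window > T_) stop(sprintf("`window` (%d) exceeds signal length (%d)", window, T_))
  if (stride < 1 || stride > window) stop("`stride` must lie in [1, window]")
  starts <- seq.int(0L, T_ - window, by = stride)
  new_segments(start = starts, end = starts + window)
}

#' @noRd
segment_lengths <- function(segments) segments$end - segments$start

# Slice signal columns for a half-open [start, end) interval.
#' @noRd
segment_slice <- function(signal, start, end) {
  signal$values[, (start + 1):end, drop = FALSE]
}

#' @noRd
segment_slices <- function(signal, segments) {
  lapply(seq_len(nrow(segments)), function(i)
    segment_slice(signal, segments$start[i], segments$end[i]))
}

#' Resample a sequence to a target length
#'
#' Per-feature linear interpolation onto `target_length` evenly spaced points
#' spanning the sequence (endpoints preserved).
#'
#' @param x Numeric matrix, features x frames.
#' @param target_length Number of output frames (>= 2).
#' @return Features x `target_length` matrix.
#' @export
resample_sequence <- function(x, target_length) {
  if (target_length < 2) stop("`target_length` must be >= 2")
  len <- ncol(x)
  if (len == target_length) return(x)
  pos <- seq(0, len - 1, length.out = target_length)
  t(apply(x, 1, function(row) approx(x = 0:(len - 1), y = row, xout = pos)$y))
}

#' Resample one segment of a signal
#' @param signal A [tasc_signal()].
#' @param segment One-row segment data frame (or list with start/end).
#' @param target_length Output length in frames.
#' @return Features x `target_length` matrix.
#' @export
resample_segment <- function(signal, segment, target_length) {
  signal <- as_tasc_signal(signal)
  resample_sequence(segment_slice(signal, segment$start[1], segment$end[1]),
                    target_length)
}

#' Read / write segment CSVs
#'
#' The on-disk format is a header-ful CSV with columns `start`, `end` and
#' optionally `label`, `score`, `tau_w`, `s_w`, `cost`. External
#' initializations produced by other frameworks need only `start,end[,label]`.
#'
#' @param path CSV path.
#' @param n_frames Optional signal length for validation.
#' @return A segment data frame.
#' @export
read_segments_csv <- function(path, n_frames = NULL) {
  df <- read.csv(path)
  if (!all(c("start", "end") %in% names(df)))
    stop(sprintf("%s: segment CSV must have 'start' and 'end' columns", path))
  seg <- new_segments(df$start, df$end,
                      label = if ("label" %in% names(df)) df$label else NA,
                      score = if ("score" %in% names(df)) df$score else NA,
                      tau_w = if ("tau_w" %in% names(df)) df$tau_w else NA,
                      s_w = if ("s_w" %in% names(df)) df$s_w else NA,
                      cost = if ("cost" %in% names(df)) df$cost else NA)
  validate_segments(seg, n_frames = n_frames)
  seg
}

#' @rdname read_segments_csv
#' @param segments Segment data frame to write.
#' @export
write_segments_csv <- function(segments, path) {
  write.csv(segments, path, row.names = FALSE)
  invisible(path)
}
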