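#' Frame weights for the variable-length weighted Euclidean distance
#'
#' Weights are 1 plus a symmetric Hamming window
#' (`0.54 - 0.46 cos(2 pi n / (N - 1))`) over the first `min(len_x, len_y)`
#' frames, and exactly 1 over the padded tail, emphasizing the temporal
#' center of the shorter sequence while keeping the padded tail at baseline.
#'
#' @param len_x,len_y Lengths of the two sequences (>= 2).
#' @return List with `weights` (length `maxlen`), `minlen`, `maxlen`.
#' @export
build_weights <- function(len_x, len_y) {
  if (len_x < 2 || len_y < 2) stop("sequence lengths must be >= 2")
  minlen <- min(len_x, len_y); maxlen <- max(len_x, len_y)
  list(weights = as.numeric(cpp_raised_hamming(minlen, maxlen)),
       minlen = minlen, maxlen = maxlen)
}

#' Weighted Euclidean distance between sequences of possibly unequal length
#'
#' The shorter sequence is tail-padded with its own per-feature median plus a
#' tiny epsilon up to the longer length; the cost is the square root of the
#' weighted sum of squared differences over all features and frames, using
#' [build_weights()]. Symmetric for equal-length inputs and zero only for
#' identical equal-length inputs.
#'
#' @param x,y Numeric matrices, features x frames, same feature count.
#' @return Non-negative scalar distance.
#' @export
weighted_euclidean <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) < 2 || ncol(y) < 2) stop("sequences must span at least 2 frames")
  cpp_weighted_euclidean(x, y)
}

#' Linear warp of a sequence
#'
#' Samples `out_length` evenly spaced normalized times `t` in `[0, 1)`; the
#' source position is `(tau_w + t * s_w) * domain_length` on the frame axis
#' of `x`, linearly interpolated between flanking frames and clamped to
#' `[0, len_x - 1]`. `tau_w` is thus expressed in the normalized time domain
#' (a shift of 0.1 moves the content by 10\% of `domain_length` frames).
#'
#' @param x Numeric matrix, features x frames.
#' @param params Numeric `c(tau_w, s_w)` or an `alignment_params` object.
#' @param out_length Number of output frames (>= 2).
#' @param domain_length Frame extent that normalized time is scaled by;
#'   defaults to `ncol(x)`.
#' @return Features x `out_length` matrix.
#' @export
warp_sequence <- function(x, params, out_length, domain_length = ncol(x)) {
  p <- as_align_params(params)
  cpp_warp_sequence(as.matrix(x), p$tau_w, p$s_w, as.integer(out_length),
                    domain_length)
}

#' Warping penalty
#'
#' `r = arctan(|tau_w|) + 1.5 * arctan(|s_w - 1|)`: zero only at the identity
#' transform, with the time-scale term penalized more heavily than the shift.
#'
#' @param tau_w Shift (normalized time units).
#' @param s_w Time-scale slope.
#' @return Non-negative penalty (vectorized over inputs).
#' @export
warp_penalty <- function(tau_w, s_w) {
  atan(abs(tau_w)) + 1.5 * atan(abs(s_w - 1))
}

#' Penalized alignment loss
#'
#' `loss = weighted_euclidean(warp(query), template) + alpha * r`, where the
#' query is warped onto the template's length (normalized time scaled by the
#' query's own length). `alpha = 0` gives the pure weighted distance.
#'
#' Because the warp acts in normalized time, a slope of 1 maps the *whole*
#' query onto the template whatever their lengths, so the raw parameters do
#' not measure real time-dilation when lengths differ. With the default
#' `penalty_scale = "effective"` the penalty is evaluated on the
#' length-corrected pair `(tau_w * r, s_w * r)` with `r = len_q / len_t`,
#' so that playing content at the same real speed is the zero-penalty point
#' and squeezing a longer query is penalized as the warp it is.
#' `"raw"` penalizes the normalized-domain parameters as printed. The two
#' coincide for equal lengths.
#'
#' @param query,template Numeric matrices, features x frames.
#' @param params `c(tau_w, s_w)` or an `alignment_params` object.
#' @param alpha Non-negative penalty weight.
#' @param penalty_scale `"effective"` (default) or `"raw"`; see Details.
#' @return Scalar loss.
#' @export
alignment_loss <- function(query, template, params, alpha = 0,
                           penalty_scale = c("effective", "raw")) {
  if (alpha < 0) stop("`alpha` must be >= 0")
  penalty_scale <- match.arg(penalty_scale)
  p <- as_align_params(params)
  cpp_alignment_loss(as.matrix(query), as.matrix(template), p$tau_w, p$s_w,
                     alpha, penalty_scale == "effective")
}

#' Optimizer settings for linear alignment
#'
#' The optimizer samples the bounded `(tau_w, s_w)` box on a deterministic
#' coarse grid, then refines the best starts (plus the identity transform)
#' with Nelder-Mead, mirroring global-sampling-plus-local-polish strategies
#' for low-dimensional bounded minimization.
#'
#' @param n_tau,n_s Coarse-grid resolution along each axis.
#' @param n_refine Number of best starts refined locally.
#' @param maxit,tol Nelder-Mead iteration cap and convergence tolerance.
#' @return List of settings for [linear_align()].
#' @export
align_control <- function(n_tau = 11, n_s = 15, n_refine = 4, maxit = 200,
                          tol = 1e-9) {
  list(n_tau = as.integer(n_tau), n_s = as.integer(n_s),
       n_refine = as.integer(n_refine), maxit = as.integer(maxit), tol = tol)
}

#' @noRd
as_align_params <- function(params) {
  if (inherits(params, "alignment_params")) return(params)
  if (is.numeric(params) && length(params) >= 2)
    return(alignment_params(params[[1]], params[[2]]))
  if (is.list(params) && all(c("tau_w", "s_w") %in% names(params)))
    return(alignment_params(params$tau_w, params$s_w, params$cost %||% NA_real_))
  stop("cannot interpret `params` as (tau_w, s_w)")
}

#' Alignment parameter pair
#' @param tau_w Shift in normalized time.
#' @param s_w Positive time-scale slope.
#' @param cost Minimized loss, if known.
#' @param fallback Whether the result came from the grid-search fallback.
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(tau_w, s_w, cost = NA_real_, fallback = FALSE) {
  if (s_w <= 0) stop("`s_w` must be positive")
  structure(list(tau_w = tau_w, s_w = s_w, cost = cost, fallback = fallback),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf("<alignment_params> tau_w = %.4f, s_w = %.4f, cost = %.6g%s\n",
              x$tau_w, x$s_w, x$cost, if (isTRUE(x$fallback)) " (grid fallback)" else ""))
  invisible(x)
}

#' Penalized linear alignment of a query onto a template
#'
#' Finds the `(tau_w, s_w)` pair inside the given box minimizing
#' [alignment_loss()], i.e. the shift and uniform time-scale under which the
#' warped query best matches the template. Deterministic for fixed inputs
#' and settings; falls back to a dense grid search (flagged in the result) if
#' the sampled optimization returns a non-finite loss.
#'
#' @param query,template Numeric matrices, features x frames.
#' @param alpha Non-negative penalty weight.
#' @param tau_bounds,s_bounds Search box; `s_bounds` must be strictly
#'   positive. Defaults cover the generation-scale warps with margin.
#' @param control Optimizer settings from [align_control()].
#' @return An [alignment_params()] whose `cost` equals the loss at the
#'   returned parameters, plus `tau_frames = tau_w * ncol(query)`.
#' @export
linear_align <- function(query, template, alpha = 0,
                         tau_bounds = c(-0.25, 0.25), s_bounds = c(0.5, 2),
                         control = align_control(),
                         penalty_scale = c("effective", "raw")) {
  query <- as.matrix(query); template <- as.matrix(template)
  penalty_scale <- match.arg(penalty_scale)
  eff <- penalty_scale == "effective"
  if (s_bounds[1] <= 0) stop("`s_bounds` must be strictly positive")
  if (tau_bounds[1] > tau_bounds[2] || s_bounds[1] > s_bounds[2])
    stop("bounds must be non-empty")
  res <- cpp_linear_align(query, template, alpha,
                          tau_bounds[1], tau_bounds[2], s_bounds[1], s_bounds[2],
                          control$n_tau, control$n_s, control$n_refine,
                          control$maxit, control$tol, eff)
  fallback <- FALSE
  if (!is.finite(res[["cost"]])) {
    res <- cpp_grid_align(query, template, alpha,
                          seq(tau_bounds[1], tau_bounds[2], length.out = 101),
                          seq(s_bounds[1], s_bounds[2], length.out = 101), eff)
    fallback <- TRUE
  }
  out <- alignment_params(res[["tau_w"]], res[["s_w"]], res[["cost"]],
                          fallback = fallback)
  out$tau_frames <- out$tau_w * ncol(query)
  out
}

#' Exhaustive grid-search alignment
#'
#' Evaluates the loss at every point of an explicit parameter grid and
#' returns the minimizer. Serves as the brute-force oracle for
#' [linear_align()] and as its fallback path.
#'
#' @inheritParams linear_align
#' @param tau_grid,s_grid Explicit parameter grids.
#' @return An [alignment_params()].
#' @export
grid_align <- function(query, template, alpha = 0,
                       tau_grid = seq(-0.25, 0.25, by = 0.002),
                       s_grid = seq(0.5, 2, by = 0.002),
                       penalty_scale = c("effective", "raw")) {
  penalty_scale <- match.arg(penalty_scale)
  res <- cpp_grid_align(as.matrix(query), as.matrix(template), alpha,
                        tau_grid, s_grid, penalty_scale == "effective")
  alignment_params(res[["tau_w"]], res[["s_w"]], res[["cost"]])
}
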