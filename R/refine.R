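#' Remove outlying cluster members
#'
#' Pairwise weighted Euclidean distances are computed between all members of
#' a cluster; a member is removed when its mean distance to the others
#' exceeds the center of the per-member mean distances by more than `gamma`
#' standard deviations. Statistics are those computed before removal and
#' later drive gap reassignment. Clusters with fewer than two members pass
#' through unchanged, flagged.
#'
#' @param members List of feature x frame matrices (the member sequences).
#' @param gamma Positive standard-deviation factor; larger keeps more.
#' @param center `"mean"` (default) or `"median"` center of the per-member
#'   mean-distance distribution.
#' @return List with integer `kept` and `removed` indices, `mean_distance`,
#'   `distance_std`, and logical `degenerate` (cluster too small to test).
#' @export
remove_outliers <- function(members, gamma, center = c("mean", "median")) {
  center <- match.arg(center)
  n <- length(members)
  if (n < 2)
    return(list(kept = seq_len(n), removed = integer(0),
                mean_distance = NA_real_, distance_std = NA_real_,
                degenerate = TRUE))
  dmat <- cpp_pairwise_wdist(members)
  di <- rowSums(dmat) / (n - 1)
  ctr <- if (center == "mean") mean(di) else median(di)
  s <- sd(di)
  removed <- which(di > ctr + gamma * s)
  list(kept = setdiff(seq_len(n), removed), removed = removed,
       mean_distance = ctr, distance_std = s, degenerate = FALSE)
}

#' Cluster centroid sequence
#'
#' Members are resampled to a common length, then combined element-wise by
#' median (default) or mean. With `existing = TRUE` the actual member
#' closest (weighted Euclidean) to that average is returned instead of the
#' average itself, guaranteeing the centroid is a realizable sequence.
#'
#' @param members Non-empty list of feature x frame matrices.
#' @param method `"median"` or `"mean"`.
#' @param existing Return the nearest actual member rather than the average.
#' @param target_length Common length; defaults to the rounded mean member
#'   length.
#' @return Features x `target_length` matrix.
#' @export
compute_centroid <- function(members, method = c("median", "mean"),
                             existing = TRUE, target_length = NULL) {
  method <- match.arg(method)
  if (length(members) == 0) stop("cannot compute the centroid of an empty cluster")
  tl <- target_length %||% max(2L, round(mean(vapply(members, ncol, 1L))))
  res <- lapply(members, resample_sequence, target_length = tl)
  if (length(res) == 1) return(res[[1]])
  arr <- array(unlist(res), dim = c(nrow(res[[1]]), tl, length(res)))
  avg <- apply(arr, c(1, 2), if (method == "median") median else mean)
  if (!existing) return(avg)
  d <- vapply(res, weighted_euclidean, numeric(1), y = avg)
  res[[which.min(d)]]
}

#' Temporal-neighbor variants of a segment
#'
#' Every candidate re-segmentation `(start + m, end + m + l)` for `m` over
#' the offset range `M` and `l` over the length-delta range `L` (both
#' inclusive). Variants falling outside `[0, T)` or shorter than 2 frames
#' are marked invalid and never selected.
#'
#' @param segment One-row segment data frame.
#' @param M Integer pair `(m_min, m_max)` of start offsets.
#' @param L Integer pair `(l_min, l_max)` of length deltas.
#' @param n_frames Signal length T.
#' @return Data frame with columns `m`, `l`, `start`, `end`, `valid`
#'   (grid size `(m_max - m_min + 1) * (l_max - l_min + 1)`).
#' @export
generate_variants <- function(segment, M, L, n_frames) {
  if (M[1] > M[2] || L[1] > L[2]) stop("invalid M or L range")
  g <- expand.grid(m = as.integer(M[1]:M[2]), l = as.integer(L[1]:L[2]))
  start <- segment$start[1] + g$m
  end <- segment$end[1] + g$m + g$l
  data.frame(m = g$m, l = g$l, start = start, end = end,
             valid = start >= 0 & end <= n_frames & (end - start) >= 2)
}

#' Score variants against a cluster centroid
#'
#' Aligns every valid variant's signal content onto the centroid with
#' [linear_align()] and records the minimized cost and warp parameters.
#' Invalid variants keep `NA` cost (score `-Inf` downstream).
#'
#' @param variants Variant grid from [generate_variants()].
#' @param signal A [tasc_signal()].
#' @param centroid Features x frames centroid matrix.
#' @param alpha Penalty weight for this epoch.
#' @param tau_bounds,s_bounds Alignment search box.
#' @param control [align_control()] settings (the refinement loop uses a
#'   leaner grid than the standalone default).
#' @param penalty_scale `"effective"` (default) or `"raw"`; see
#'   [alignment_loss()].
#' @return `variants` with `tau_w`, `s_w`, `cost` columns filled in.
#' @export
score_variants <- function(variants, signal, centroid, alpha,
                           tau_bounds = c(-0.25, 0.25), s_bounds = c(0.5, 2),
                           control = align_control(),
                           penalty_scale = c("effective", "raw")) {
  signal <- as_tasc_signal(signal)
  penalty_scale <- match.arg(penalty_scale)
  res <- cpp_align_slices(signal$values,
                          as.integer(variants$start), as.integer(variants$end),
                          as.matrix(centroid), alpha,
                          tau_bounds[1], tau_bounds[2], s_bounds[1], s_bounds[2],
                          control$n_tau, control$n_s, control$n_refine,
                          control$maxit, control$tol,
                          penalty_scale == "effective")
  variants$tau_w <- ifelse(variants$valid, res[, "tau_w"], NA_real_)
  variants$s_w <- ifelse(variants$valid, res[, "s_w"], NA_real_)
  variants$cost <- ifelse(variants$valid, res[, "cost"], NA_real_)
  variants
}

#' Convert alignment costs to selection scores
#'
#' Costs are normalized per cluster (divided by the cluster's maximum cost,
#' guarding against imbalance-driven skew) and deducted from 1, so scores
#' lie in `[0, 1]`, lower cost means higher score, and each cluster's
#' worst-cost candidate scores exactly 0. An all-zero-cost cluster scores 1
#' throughout. `NA` costs map to `-Inf`.
#'
#' @param costs Non-negative numeric costs.
#' @param cluster_ids Cluster id per cost (any vector usable as a factor).
#' @return Numeric scores.
#' @export
costs_to_scores <- function(costs, cluster_ids) {
  if (length(costs) != length(cluster_ids))
    stop("`costs` and `cluster_ids` must have the same length")
  scores <- rep(-Inf, length(costs))
  ok <- !is.na(costs)
  for (cl in unique(cluster_ids[ok])) {
    i <- ok & cluster_ids == cl
    mx <- max(costs[i])
    scores[i] <- if (mx == 0) 1 else 1 - costs[i] / mx
  }
  scores
}

#' Maximum-score selection of non-overlapping intervals
#'
#' Weighted-interval-scheduling dynamic program: among candidate half-open
#' intervals with scores, returns a subset of pairwise non-overlapping
#' intervals maximizing the total score (candidates are sorted by end and a
#' sorted-boundary binary search provides the O(log n) predecessor lookup).
#' Ties resolve deterministically, keeping zero-score candidates when they
#' conflict with nothing better.
#'
#' @param start,end Integer interval boundaries (half-open).
#' @param score Finite scores; `-Inf`/`NA` rows are discarded up front.
#' @return Integer indices (into the input order) of the selected subset,
#'   sorted by start.
#' @export
select_nonoverlapping <- function(start, end, score) {
  keep <- is.finite(score)
  idx <- which(keep)
  n <- length(idx)
  if (n == 0) return(integer(0))
  s <- start[idx]; e <- end[idx]; w <- score[idx]
  ord <- order(e, s, idx)
  s <- s[ord]; e <- e[ord]; w <- w[ord]; orig <- idx[ord]
  # p[i]: number of intervals (in end-sorted order) ending at or before s[i]
  p <- findInterval(s, e)
  dp <- numeric(n + 1)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- w[i] + dp[p[i] + 1]
    take[i] <- with_i >= dp[i]
    dp[i + 1] <- max(dp[i], with_i)
  }
  sel <- integer(0)
  i <- n
  while (i >= 1) {
    if (take[i] && w[i] + dp[p[i] + 1] >= dp[i]) {
      sel <- c(sel, orig[i])
      i <- p[i]
    } else {
      i <- i - 1
    }
  }
  sel[order(start[sel], end[sel], sel)]
}

#' Rescan large unassigned gaps against the cluster centroids
#'
#' A gap (a stretch of frames not covered by any selected segment,
#' including the signal's flanks) is significantly large when its duration
#' is at least the mean selected-segment length. Windows of that mean
#' length slide through each such gap; a window whose minimum weighted
#' Euclidean distance to the centroids beats that cluster's mean
#' intra-cluster distance becomes a candidate, and candidates within a gap
#' are resolved by [costs_to_scores()] + [select_nonoverlapping()].
#'
#' Candidate windows must also satisfy the framework's segment-validity
#' rule when an activity mask is supplied: windows lying less than
#' `min_active_fraction` inside activity periods are never admitted, which
#' keeps quiet baseline stretches from being re-labeled as motifs.
#'
#' @param selected Non-overlapping, sorted segment data frame.
#' @param signal A [tasc_signal()].
#' @param clusters List of per-cluster lists with elements `label`,
#'   `centroid`, `mean_distance` (from [remove_outliers()]).
#' @param mean_segment_length Mean selected length, in frames.
#' @param stride Window hop; defaults to a quarter of the window.
#' @param mask Optional `tasc_activity` mask gating candidate windows.
#' @param min_active_fraction Required active fraction under `mask`.
#' @return `selected` plus any accepted gap windows, globally
#'   non-overlapping and sorted by start.
#' @export
reassign_gaps <- function(selected, signal, clusters, mean_segment_length,
                          stride = max(1L, round(mean_segment_length / 4)),
                          mask = NULL, min_active_fraction = 0.9) {
  signal <- as_tasc_signal(signal)
  T_ <- n_frames(signal)
  wlen <- as.integer(round(mean_segment_length))
  if (wlen < 2 || length(clusters) == 0) return(selected)
  usable <- Filter(function(cl) is.finite(cl$mean_distance %||% NA_real_), clusters)
  if (length(usable) == 0) return(selected)
  selected <- selected[order(selected$start), , drop = FALSE]
  bounds <- c(0L, as.vector(rbind(selected$start, selected$end)), T_)
  gaps <- matrix(bounds, ncol = 2, byrow = TRUE)  # [start, end) of each gap
  added <- list()
  for (g in seq_len(nrow(gaps))) {
    glen <- gaps[g, 2] - gaps[g, 1]
    if (glen < mean_segment_length) next
    starts <- unique(c(seq.int(gaps[g, 1], gaps[g, 2] - wlen, by = stride),
                       gaps[g, 2] - wlen))
    if (!is.null(mask)) {
      wins <- new_segments(starts, starts + wlen)
      ok <- filter_valid_segments(wins, mask, min_active_fraction)
      starts <- ok$start
    }
    cand <- list()
    for (st in starts) {
      win <- segment_slice(signal, st, st + wlen)
      d <- vapply(usable, function(cl) weighted_euclidean(win, cl$centroid),
                  numeric(1))
      best <- which.min(d)
      if (d[best] < usable[[best]]$mean_distance)
        cand[[length(cand) + 1]] <- data.frame(start = st, end = st + wlen,
                                               label = usable[[best]]$label,
                                               cost = d[best])
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    cand$score <- costs_to_scores(cand$cost, cand$label)
    pick <- select_nonoverlapping(cand$start, cand$end, cand$score)
    if (length(pick))
      added[[length(added) + 1]] <- cand[pick, , drop = FALSE]
  }
  if (length(added) == 0) return(selected)
  added <- do.call(rbind, added)
  # gap windows carry no alignment params; their cost is the raw distance
  out <- rbind(selected,
               new_segments(added$start, added$end, label = added$label,
                            score = added$score, tau_w = NA, s_w = NA,
                            cost = added$cost))
  out[order(out$start), , drop = FALSE]
}
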