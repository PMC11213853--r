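#' Intersection over union of two frame intervals
#'
#' Half-open intervals; symmetric, 1 iff identical, 0 when disjoint.
#'
#' @param a,b Length-2 numeric vectors `c(start, end)` (or 1-row segment
#'   data frames).
#' @return IoU in `[0, 1]`.
#' @export
interval_iou <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  inter / union
}

#' @noRd
as_interval <- function(x) {
  if (is.data.frame(x)) return(c(x$start[1], x$end[1]))
  if (length(x) < 2) stop("an interval needs a start and an end")
  c(x[[1]], x[[2]])
}

#' Match predicted segments to ground truth
#'
#' Greedy one-to-one matching in decreasing-IoU order (ties broken by
#' earlier truth start, then earlier predicted start). A pair is admissible
#' when the intersection covers at least half the ground-truth segment's
#' duration (`rule = "half_duration"`, the default) or when its IoU is at
#' least `min_iou` (`rule = "iou"`).
#'
#' @param pred,truth Segment data frames (non-overlapping within each list).
#' @param rule Correspondence rule; see Details.
#' @param min_iou IoU cutoff for `rule = "iou"`.
#' @return Data frame with columns `pred`, `truth` (row indices), `iou`,
#'   `intersection`.
#' @export
match_segments <- function(pred, truth, rule = c("half_duration", "iou"),
                           min_iou = 0.5) {
  rule <- match.arg(rule)
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0)
    return(data.frame(pred = integer(0), truth = integer(0),
                      iou = numeric(0), intersection = numeric(0)))
  ps <- pred$start; pe <- pred$end; ts <- truth$start; te <- truth$end
  inter <- outer(pe, te, pmin) - outer(ps, ts, pmax)
  inter[inter < 0] <- 0
  uni <- outer(pe - ps, te - ts, "+") - inter
  iou <- inter / uni
  admissible <- if (rule == "half_duration") {
    inter >= 0.5 * matrix(te - ts, np, nt, byrow = TRUE)
  } else {
    iou >= min_iou
  }
  admissible <- admissible & iou > 0
  cand <- which(admissible, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(pred = integer(0), truth = integer(0),
                      iou = numeric(0), intersection = numeric(0)))
  ciou <- iou[cand]
  ord <- order(-ciou, ts[cand[, 2]], ps[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  used_p <- logical(np); used_t <- logical(nt)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_p[i] || used_t[j]) next
    used_p[i] <- TRUE; used_t[j] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(pred = i, truth = j,
                                           iou = iou[i, j],
                                           intersection = inter[i, j])
  }
  do.call(rbind, rows)
}

#' Cumulative L1 distance between corresponding boundaries
#'
#' Sum over matched pairs of `|start_pred - start_truth| +
#' |end_pred - end_truth|`, in frames. Zero (with a warning) for an empty
#' matching.
#'
#' @param matches Output of [match_segments()].
#' @param pred,truth The segment data frames the matching refers to.
#' @return Non-negative total, in frames.
#' @export
boundary_l1 <- function(matches, pred, truth) {
  if (nrow(matches) == 0) {
    warning("empty matching: boundary L1 reported as 0")
    return(0)
  }
  sum(abs(pred$start[matches$pred] - truth$start[matches$truth]) +
        abs(pred$end[matches$pred] - truth$end[matches$truth]))
}

#' Mean IoU of a segmentation against ground truth
#'
#' @param pred,truth Segment data frames.
#' @param matches Optional precomputed [match_segments()] result.
#' @param unmatched_zero Count unmatched truth segments as IoU 0 (default);
#'   otherwise average over matched pairs only.
#' @inheritParams match_segments
#' @return Mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(pred, truth, matches = NULL, unmatched_zero = TRUE,
                     rule = "half_duration") {
  matches <- matches %||% match_segments(pred, truth, rule = rule)
  if (unmatched_zero) {
    if (nrow(truth) == 0) return(NA_real_)
    sum(matches$iou) / nrow(truth)
  } else {
    if (nrow(matches) == 0) return(0)
    mean(matches$iou)
  }
}

# Maximal-trace assignment of rows to columns of a non-negative count
# matrix: exact subset-DP up to 16 columns, greedy beyond.
#' @noRd
solve_assignment <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nc <= 16 && nr <= 25) {
    full <- 2^nc
    best <- matrix(-Inf, nr + 1, full)
    best[1, 1] <- 0
    choice <- array(NA_integer_, dim = c(nr + 1, full))
    for (i in seq_len(nr)) {
      for (mask in 0:(full - 1)) {
        v <- best[i, mask + 1]
        if (!is.finite(v)) next
        # leave row i unassigned
        if (v > best[i + 1, mask + 1]) {
          best[i + 1, mask + 1] <- v
          choice[i + 1, mask + 1] <- 0L
        }
        for (j in seq_len(nc)) {
          bit <- bitwShiftL(1L, j - 1L)
          if (bitwAnd(mask, bit) > 0) next
          nm <- mask + bit
          nv <- v + m[i, j]
          if (nv > best[i + 1, nm + 1]) {
            best[i + 1, nm + 1] <- nv
            choice[i + 1, nm + 1] <- j
          }
        }
      }
    }
    mask <- which.max(best[nr + 1, ]) - 1L
    assign <- integer(nr)
    for (i in nr:1) {
      j <- choice[i + 1, mask + 1]
      assign[i] <- j
      if (!is.na(j) && j > 0) mask <- mask - bitwShiftL(1L, j - 1L)
    }
    assign[assign == 0L] <- NA_integer_
    return(assign)
  }
  assign <- rep(NA_integer_, nr)
  mm <- m
  for (step in seq_len(min(nr, nc))) {
    w <- which(mm == max(mm), arr.ind = TRUE)[1, ]
    if (mm[w[1], w[2]] < 0) break
    assign[w[1]] <- w[2]
    mm[w[1], ] <- -1
    mm[, w[2]] <- -1
  }
  assign
}

#' Confusion matrix and recall with cluster-to-class resolution
#'
#' Cluster labels carry no intrinsic order, so predicted clusters are first
#' mapped onto truth classes by a maximal-agreement assignment on the
#' match-count matrix. The confusion matrix has one row per predicted
#' cluster plus an "unmatched" row and one column per truth class plus an
#' "unmatched" column, all entries divided by the number of true segments.
#' Recall is the fraction of true segments that are both matched and
#' correctly labeled after the mapping.
#'
#' @param pred,truth Segment data frames; both need a `label` column.
#' @param matches Optional precomputed [match_segments()] result.
#' @inheritParams match_segments
#' @return List with `confusion` (normalized matrix), `recall`, and the
#'   cluster-to-class `mapping` (named integer vector).
#' @export
confusion_and_recall <- function(pred, truth, matches = NULL,
                                 rule = "half_duration") {
  matches <- matches %||% match_segments(pred, truth, rule = rule)
  ks <- sort(unique(pred$label[!is.na(pred$label)]))
  cs <- sort(unique(truth$label))
  nk <- length(ks); nc <- length(cs); nt <- nrow(truth)
  counts <- matrix(0, nk, nc, dimnames = list(ks, cs))
  if (nrow(matches) > 0) {
    for (r in seq_len(nrow(matches))) {
      k <- match(pred$label[matches$pred[r]], ks)
      cl <- match(truth$label[matches$truth[r]], cs)
      if (!is.na(k) && !is.na(cl)) counts[k, cl] <- counts[k, cl] + 1
    }
  }
  mapping <- solve_assignment(counts)
  names(mapping) <- ks
  conf <- matrix(0, nk + 1, nc + 1,
                 dimnames = list(c(as.character(ks), "unmatched"),
                                 c(as.character(cs), "unmatched")))
  conf[seq_len(nk), seq_len(nc)] <- counts
  matched_truth <- if (nrow(matches)) matches$truth else integer(0)
  for (j in setdiff(seq_len(nt), matched_truth)) {
    cl <- match(truth$label[j], cs)
    conf[nk + 1, cl] <- conf[nk + 1, cl] + 1
  }
  matched_pred <- if (nrow(matches)) matches$pred else integer(0)
  for (i in setdiff(seq_len(nrow(pred)), matched_pred)) {
    k <- match(pred$label[i], ks)
    if (!is.na(k)) conf[k, nc + 1] <- conf[k, nc + 1] + 1
  }
  correct <- 0
  if (nrow(matches) > 0) {
    for (r in seq_len(nrow(matches))) {
      k <- match(pred$label[matches$pred[r]], ks)
      if (!is.na(k) && !is.na(mapping[k]) &&
          cs[mapping[k]] == truth$label[matches$truth[r]])
        correct <- correct + 1
    }
  }
  list(confusion = conf / nt, recall = correct / nt, mapping = mapping)
}

#' Internal clustering quality indices
#'
#' Mean silhouette width (via the `cluster` package) and the
#' Calinski-Harabasz variance-ratio criterion
#' `(B/(K-1)) / (W/(N-K))`, both on the embedded points.
#'
#' @param embeddings N x d numeric matrix.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return List with `silhouette` (in `[-1, 1]`) and `calinski_harabasz`.
#' @export
clustering_indices <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  n <- nrow(embeddings)
  if (k < 2) stop("clustering indices require at least 2 clusters")
  if (n <= k) stop("need more points than clusters")
  sil <- mean(cluster::silhouette(labels, dist(embeddings))[, "sil_width"])
  mu <- colMeans(embeddings)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    pts <- embeddings[labels == g, , drop = FALSE]
    cg <- colMeans(pts)
    W <- W + sum(sweep(pts, 2, cg)^2)
    B <- B + nrow(pts) * sum((cg - mu)^2)
  }
  ch <- (B / (k - 1)) / (W / (n - k))
  list(silhouette = sil, calinski_harabasz = ch)
}

#' One-call segmentation evaluation report
#'
#' @param pred,truth Segment data frames (truth labeled).
#' @inheritParams match_segments
#' @return List with `mean_iou`, `boundary_l1`, `recall`, `n_matched`,
#'   `confusion`, `matches`.
#' @export
evaluate_segmentation <- function(pred, truth, rule = "half_duration") {
  validate_segments(truth, require_nonoverlap = TRUE)
  matches <- match_segments(pred, truth, rule = rule)
  cr <- if (!is.null(pred$label) && any(!is.na(pred$label)))
    confusion_and_recall(pred, truth, matches = matches)
  else list(confusion = NULL, recall = NA_real_, mapping = NULL)
  bl1 <- if (nrow(matches) > 0) boundary_l1(matches, pred, truth) else 0
  list(mean_iou = mean_iou(pred, truth, matches = matches),
       boundary_l1 = bl1,
       recall = cr$recall, n_matched = nrow(matches),
       confusion = cr$confusion, matches = matches)
}
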