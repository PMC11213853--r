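#' Configuration of the refinement framework
#'
#' All tunable parameters of the segmentation-refinement loop. The offset
#' range `M` and length-delta range `L` define which temporal neighbors of
#' each segment are evaluated; `alpha` weights the warping penalty (larger
#' means less warping allowed) and `gamma` sets the outlier cutoff in
#' standard deviations of within-cluster distances. `L` and `alpha` accept
#' per-epoch schedules: a function of the epoch number, a list (`L`) or
#' vector (`alpha`) indexed by epoch, or a single value used throughout.
#'
#' @param window Initial naive window size, in frames.
#' @param stride Hop of the initial segmentation; defaults to `window / 3`
#'   (rounded), giving overlapping candidate windows whose overlaps the
#'   membership-score selection resolves.
#' @param n_clusters Number of clusters K for the default fuzzy c-means.
#' @param n_components PCA components for the default embedder (a value in
#'   (0,1) means variance-explained fraction).
#' @param fuzziness FCM fuzzifier.
#' @param M Integer pair: range of start offsets for temporal neighbors.
#' @param L Integer pair, list of pairs, or `function(epoch)`: range of
#'   length deltas.
#' @param alpha Penalty weight: scalar, per-epoch vector, or
#'   `function(epoch)`.
#' @param gamma Outlier factor (> 0).
#' @param centroid_method `"median"` or `"mean"` element-wise combination.
#' @param centroid_existing Use the member closest to the average as the
#'   centroid (default) rather than the average itself.
#' @param centroid_aligned Compute centroids from the members'
#'   warp-aligned content (each member warped by its stored parameters)
#'   rather than raw slices (default FALSE: repeated re-warping against an
#'   evolving centroid frame can accumulate phase drift; the option is
#'   retained for externally anchored centroid frames).
#' @param outlier_center Center of the distance distribution the gamma rule
#'   is anchored to: `"mean"` (default) or `"median"`.
#' @param epochs Number of refinement epochs.
#' @param seed Seed covering every stochastic step.
#' @param use_activity Gate initial windows on detected activity periods.
#' @param activity Settings for [detect_activity_periods()].
#' @param min_active_fraction Validity threshold for initial windows.
#' @param dilution `NULL`, or a list with `max_overlap_fraction` and
#'   optionally `latent_radius` to thin the initial segmentation.
#' @param gap_fill Run gap reassignment each epoch (default TRUE).
#' @param gap_stride_frac Gap-scan stride as a fraction of the mean segment
#'   length.
#' @param tau_bounds,s_bounds Alignment search box.
#' @param align [align_control()] used inside the refinement loop (leaner
#'   than the standalone alignment default, since the loop performs tens of
#'   thousands of bounded optimizations per epoch).
#' @param penalty_scale How the warp penalty treats unequal lengths during
#'   variant scoring: `"effective"` (default) or `"raw"`; see
#'   [alignment_loss()].
#' @param tie_break Deterministic selection tie-break: each variant's score
#'   is reduced by `tie_break * (|m| + |l|)`, so among cost-equivalent
#'   re-segmentations (e.g. a segment extended into excluded baseline) the
#'   least perturbed one wins. Orders of magnitude below real score
#'   differences; set 0 to disable.
#' @param convergence_frac,convergence_frames Stop early when fewer than
#'   this fraction of segments move either boundary by more than this many
#'   frames between epochs.
#' @return Object of class `tasc_config`.
#' @export
tasc_config <- function(window = 90, stride = NULL, n_clusters = 5,
                        n_components = 10, fuzziness = 1.5,
                        M = c(-10, 10), L = c(-1, 10), alpha = 1, gamma = 4,
                        centroid_method = c("median", "mean"),
                        centroid_existing = TRUE,
                        centroid_aligned = FALSE,
                        outlier_center = c("mean", "median"),
                        epochs = 10, seed = 1L,
                        use_activity = TRUE,
                        activity = list(cutoff_hz = 3, threshold_quantile = 0.25,
                                        min_period_frames = 10),
                        min_active_fraction = 0.9,
                        dilution = NULL,
                        gap_fill = TRUE, gap_stride_frac = 0.25,
                        tau_bounds = c(-0.25, 0.25), s_bounds = c(0.5, 2),
                        align = align_control(n_tau = 5, n_s = 7, n_refine = 1,
                                              maxit = 100, tol = 1e-8),
                        penalty_scale = c("effective", "raw"),
                        tie_break = 1e-4,
                        convergence_frac = 0.01, convergence_frames = 1) {
  if (gamma <= 0) stop("`gamma` must be positive")
  if (epochs < 0) stop("`epochs` must be >= 0")
  if (is.numeric(M) && M[1] > M[2]) stop("`M` range is empty")
  cfg <- list(window = as.integer(window),
              stride = as.integer(stride %||% max(1, round(window / 3))),
              n_clusters = as.integer(n_clusters),
              n_components = n_components, fuzziness = fuzziness,
              M = M, L = L, alpha = alpha, gamma = gamma,
              centroid_method = match.arg(centroid_method),
              centroid_existing = centroid_existing,
              centroid_aligned = centroid_aligned,
              outlier_center = match.arg(outlier_center),
              epochs = as.integer(epochs), seed = as.integer(seed),
              use_activity = use_activity, activity = activity,
              min_active_fraction = min_active_fraction,
              dilution = dilution,
              gap_fill = gap_fill, gap_stride_frac = gap_stride_frac,
              tau_bounds = tau_bounds, s_bounds = s_bounds, align = align,
              penalty_scale = match.arg(penalty_scale),
              tie_break = tie_break,
              convergence_frac = convergence_frac,
              convergence_frames = convergence_frames)
  structure(cfg, class = "tasc_config")
}

#' Worked configuration for the semi-synthetic benchmark
#'
#' 90-frame naive windows tiled end to end (the benchmark's original
#' initialization; the package-wide default uses overlapping windows
#' instead), 10-component PCA, 5-cluster FCM with median existing
#' centroids, `M = (-10, 10)`, `L(n) = (-n, 10)`, `alpha = 10^R(n)` with
#' `R` evenly spaced over `[0.5, -1]` across the epochs, and `gamma = 4`
#' (chosen to preserve every cluster member when the initial clustering is
#' sound).
#'
#' @param epochs Number of epochs (default 10).
#' @param ... Overrides passed on to [tasc_config()].
#' @return A `tasc_config`.
#' @export
semisynthetic_config <- function(epochs = 10, ...) {
  args <- list(window = 90, stride = 90, n_clusters = 5, n_components = 10,
               M = c(-10, 10), L = function(n) c(-n, 10),
               alpha = 10^seq(0.5, -1, length.out = max(epochs, 1)),
               gamma = 4, centroid_method = "median",
               centroid_existing = TRUE, epochs = epochs)
  do.call(tasc_config, modifyList(args, list(...)))
}

#' @noRd
epoch_L <- function(config, epoch) {
  L <- config$L
  if (is.function(L)) return(as.integer(L(epoch)))
  if (is.list(L)) return(as.integer(L[[min(epoch, length(L))]]))
  as.integer(L)
}

#' @noRd
epoch_alpha <- function(config, epoch) {
  a <- config$alpha
  if (is.function(a)) return(a(epoch))
  a[[min(epoch, length(a))]]
}

#' Initialize the refinement state
#'
#' Normalizes the signal, detects activity periods, and either adopts an
#' external segmentation (clustering it if unlabeled) or builds the
#' internal naive one: fixed windows, validity filtering against activity,
#' optional spatiotemporal dilution, PCA embedding, fuzzy c-means, and a
#' score-based non-overlapping selection using the soft memberships.
#'
#' @param signal A [tasc_signal()] (raw; normalized internally).
#' @param config A [tasc_config()].
#' @param init Optional external segment data frame (must lie in `[0, T)`).
#' @return The initial state: list with `signal`, `mask`, `segments`,
#'   `embedding`, `embedding_labels`, `epoch = 0`.
#' @export
tasc_init <- function(signal, config = tasc_config(), init = NULL) {
  signal <- normalize_signal(as_tasc_signal(signal))
  T_ <- n_frames(signal)
  mask <- if (config$use_activity)
    do.call(detect_activity_periods, c(list(signal), config$activity)) else NULL
  if (!is.null(init)) {
    validate_segments(init, n_frames = T_)
    segments <- init
    if (!"label" %in% names(segments) || all(is.na(segments$label))) {
      emb <- embed_segments(signal, segments, pca_embedder(config$n_components))
      cl <- cluster_segments(emb, fcm_clusterer(config$n_clusters,
                                                config$fuzziness, config$seed))
      segments <- new_segments(segments$start, segments$end, label = cl$labels,
                               score = apply(cl$memberships, 1, max))
      emb_labels <- cl$labels
    } else {
      segments <- new_segments(segments$start, segments$end,
                               label = segments$label,
                               score = segments$score %||% NA_real_)
      emb <- embed_segments(signal, segments, pca_embedder(config$n_components))
      emb_labels <- segments$label
    }
  } else {
    cand <- naive_segmentation(T_, config$window, config$stride)
    if (!is.null(mask)) {
      kept <- filter_valid_segments(cand, mask, config$min_active_fraction)
      if (nrow(kept) > config$n_clusters) cand <- kept
    }
    if (nrow(cand) <= config$n_clusters)
      stop("too few valid initial windows; reduce `window` or `n_clusters`")
    emb <- embed_segments(signal, cand, pca_embedder(config$n_components),
                          target_length = config$window)
    if (!is.null(config$dilution)) {
      dil <- spatiotemporal_dilution(
        cand, emb,
        max_overlap_fraction = config$dilution$max_overlap_fraction %||% 0.5,
        latent_radius = config$dilution$latent_radius)
      keep_idx <- match(dil$start, cand$start)  # naive starts are unique
      cand <- cand[keep_idx, , drop = FALSE]
      emb <- emb[keep_idx, , drop = FALSE]
    }
    cl <- cluster_segments(emb, fcm_clusterer(config$n_clusters,
                                              config$fuzziness, config$seed))
    score <- apply(cl$memberships, 1, max)
    sel <- select_nonoverlapping(cand$start, cand$end, score)
    segments <- new_segments(cand$start[sel], cand$end[sel],
                             label = cl$labels[sel], score = score[sel])
    emb <- emb[sel, , drop = FALSE]
    emb_labels <- cl$labels[sel]
  }
  list(signal = signal, mask = mask, segments = segments,
       embedding = emb, embedding_labels = emb_labels, epoch = 0L)
}

#' One refinement epoch
#'
#' Executes, in order: per-cluster outlier removal (gamma rule), centroid
#' computation, temporal-neighbor variant generation over `M` and
#' `L(epoch)`, penalized linear alignment of every valid variant against
#' its cluster's centroid with `alpha(epoch)`, per-cluster cost-to-score
#' conversion, global non-overlapping selection, warp-alignment and
#' re-embedding/re-clustering of the selected segments (new cluster ids
#' mapped back onto the old by maximal agreement), and gap reassignment.
#'
#' @param state State from [tasc_init()] or a previous epoch.
#' @param config A [tasc_config()].
#' @param epoch Epoch number (1-based), which indexes the `L`/`alpha`
#'   schedules.
#' @return The new state, with `metrics` (one-row data frame) attached.
#' @export
run_epoch <- function(state, config, epoch = state$epoch + 1L) {
  signal <- state$signal
  T_ <- n_frames(signal)
  segments <- state$segments
  segments <- segments[!is.na(segments$label), , drop = FALSE]
  L_ep <- epoch_L(config, epoch)
  a_ep <- epoch_alpha(config, epoch)

  # outlier removal + centroids, per cluster
  labels <- sort(unique(segments$label))
  clusters <- list()
  kept_rows <- integer(0)
  for (k in labels) {
    rows <- which(segments$label == k)
    slices <- segment_slices(signal, segments[rows, , drop = FALSE])
    out <- remove_outliers(slices, config$gamma, config$outlier_center)
    if (length(out$kept) == 0) {
      warning(sprintf("cluster %d emptied by outlier removal; dropped", k))
      next
    }
    kept_rows <- c(kept_rows, rows[out$kept])
    # centroid members: phase-compensated by their stored warps when known
    members <- slices[out$kept]
    if (isTRUE(config$centroid_aligned)) {
      members <- lapply(seq_along(members), function(j) {
        r <- rows[out$kept[j]]
        tw <- segments$tau_w[r]; sw <- segments$s_w[r]
        if (is.na(tw) || is.na(sw)) return(members[[j]])
        warp_sequence(members[[j]], c(tw, sw), ncol(members[[j]]))
      })
    }
    clusters[[length(clusters) + 1]] <-
      list(label = k,
           centroid = compute_centroid(members,
                                       method = config$centroid_method,
                                       existing = config$centroid_existing),
           mean_distance = out$mean_distance,
           distance_std = out$distance_std,
           n_members = length(out$kept))
  }
  if (length(clusters) == 0) stop("no clusters survived outlier removal")
  kept <- segments[sort(kept_rows), , drop = FALSE]

  # variant generation + alignment scoring, batched per cluster; variants
  # must satisfy the same activity-validity rule as initial segments (the
  # incumbent m = l = 0 variant stays eligible so a segment cannot vanish
  # solely through the mask)
  active_cum <- if (!is.null(state$mask)) c(0, cumsum(state$mask$active)) else NULL
  var_list <- list()
  for (cl in clusters) {
    rows <- which(kept$label == cl$label)
    v <- do.call(rbind, lapply(rows, function(r) {
      g <- generate_variants(kept[r, , drop = FALSE], config$M, L_ep, T_)
      g$segment <- r
      if (!is.null(active_cum)) {
        frac <- (active_cum[pmin(g$end, T_) + 1] -
                   active_cum[pmax(g$start, 0) + 1]) / (g$end - g$start)
        ok <- frac >= config$min_active_fraction | (g$m == 0 & g$l == 0)
        g$valid <- g$valid & ok
      }
      g
    }))
    res <- cpp_align_slices(signal$values,
                            as.integer(ifelse(v$valid, v$start, 0L)),
                            as.integer(ifelse(v$valid, v$end, 0L)),
                            as.matrix(cl$centroid), a_ep,
                            config$tau_bounds[1], config$tau_bounds[2],
                            config$s_bounds[1], config$s_bounds[2],
                            config$align$n_tau, config$align$n_s,
                            config$align$n_refine, config$align$maxit,
                            config$align$tol,
                            config$penalty_scale == "effective")
    v$tau_w <- ifelse(v$valid, res[, "tau_w"], NA_real_)
    v$s_w <- ifelse(v$valid, res[, "s_w"], NA_real_)
    v$cost <- ifelse(v$valid, res[, "cost"], NA_real_)
    v$label <- cl$label
    var_list[[length(var_list) + 1]] <- v
  }
  variants <- do.call(rbind, var_list)
  variants$score <- costs_to_scores(variants$cost, variants$label) -
    config$tie_break * (abs(variants$m) + abs(variants$l))

  sel <- select_nonoverlapping(variants$start, variants$end, variants$score)
  picked <- variants[sel, , drop = FALSE]
  selected <- new_segments(picked$start, picked$end, label = picked$label,
                           score = picked$score, tau_w = picked$tau_w,
                           s_w = picked$s_w, cost = picked$cost)
  # audit record: the cluster each cost was scored against, and the alpha used
  audit <- data.frame(start = picked$start, end = picked$end,
                      tau_w = picked$tau_w, s_w = picked$s_w,
                      cost = picked$cost, scored_label = picked$label,
                      alpha = a_ep)

  # warp-align the selected segments, re-embed, re-cluster
  lbar <- max(2L, as.integer(round(mean(segment_lengths(selected)))))
  aligned <- lapply(seq_len(nrow(selected)), function(i) {
    sl <- segment_slice(signal, selected$start[i], selected$end[i])
    warp_sequence(sl, c(selected$tau_w[i], selected$s_w[i]), lbar,
                  domain_length = ncol(sl))
  })
  k_live <- length(unique(selected$label))
  emb <- embed_sequences(aligned, pca_embedder(config$n_components),
                         target_length = lbar)
  if (k_live >= 2 && nrow(emb) > k_live) {
    cl_new <- cluster_segments(emb, fcm_clusterer(k_live, config$fuzziness,
                                                  config$seed))
    if (length(unique(cl_new$labels)) < 2) {
      # degenerate re-clustering (fuzzy center collapse): keep the labels
      warning("re-clustering collapsed to one cluster; labels kept")
      emb_labels <- selected$label
      cl_new <- NULL
    }
  } else cl_new <- NULL
  if (!is.null(cl_new)) {
    old_ids <- sort(unique(selected$label))
    cont <- table(factor(cl_new$labels, levels = seq_len(k_live)),
                  factor(selected$label, levels = old_ids))
    map <- solve_assignment(unclass(cont))
    new_labels <- old_ids[map[cl_new$labels]]
    unmapped <- is.na(new_labels)
    new_labels[unmapped] <- selected$label[unmapped]
    selected$label <- new_labels
    selected$score <- apply(cl_new$memberships, 1, max)
    emb_labels <- new_labels
  } else {
    emb_labels <- selected$label
  }

  # fill significantly large gaps against the epoch's centroids
  final <- if (config$gap_fill) {
    reassign_gaps(selected, signal, clusters,
                  mean_segment_length = mean(segment_lengths(selected)),
                  stride = max(1L, round(config$gap_stride_frac *
                                           mean(segment_lengths(selected)))),
                  mask = state$mask,
                  min_active_fraction = config$min_active_fraction)
  } else selected

  # epoch metrics + boundary-stability bookkeeping
  parent <- picked$segment
  moved <- abs(picked$start - kept$start[parent]) > config$convergence_frames |
    abs(picked$end - kept$end[parent]) > config$convergence_frames
  n_changed <- sum(moved) + (nrow(segments) - length(unique(parent))) +
    (nrow(final) - nrow(selected))
  idx <- clustering_indices_safe(emb, emb_labels)
  metrics <- data.frame(epoch = epoch, n_segments = nrow(final),
                        mean_cost = mean(picked$cost),
                        silhouette = idx$silhouette,
                        calinski_harabasz = idx$calinski_harabasz,
                        frac_changed = n_changed / max(1, nrow(segments)))
  list(signal = signal, mask = state$mask, segments = final,
       embedding = emb, embedding_labels = emb_labels,
       clusters = clusters, audit = audit, epoch = as.integer(epoch),
       metrics = metrics)
}

#' @noRd
clustering_indices_safe <- function(emb, labels) {
  tryCatch(clustering_indices(emb, labels),
           error = function(e) list(silhouette = NA_real_,
                                    calinski_harabasz = NA_real_))
}

#' Run the full refinement
#'
#' Initialization (internal naive path or an external segmentation)
#' followed by refinement epochs until the configured count or until
#' boundary convergence. When ground truth is supplied, per-epoch mean IoU
#' and cumulative boundary L1 are recorded in the trace.
#'
#' @param signal A [tasc_signal()] or frames-by-features data frame.
#' @param config A [tasc_config()].
#' @param init Optional external initial segmentation (segment data frame).
#' @param truth Optional ground-truth segment data frame.
#' @return Object of class `tasc_result`: `segments` (final), `trace`
#'   (per-epoch metrics, epoch 0 = initialization), `clusters`,
#'   `embedding`, `config`, `converged`.
#' @export
run_tasc <- function(signal, config = tasc_config(), init = NULL,
                     truth = NULL) {
  local_seed(config$seed, {
    state <- tasc_init(signal, config, init = init)
    idx0 <- clustering_indices_safe(state$embedding, state$embedding_labels)
    trace <- data.frame(epoch = 0L, n_segments = nrow(state$segments),
                        mean_cost = NA_real_, silhouette = idx0$silhouette,
                        calinski_harabasz = idx0$calinski_harabasz,
                        frac_changed = NA_real_)
    trace <- append_truth_metrics(trace, state$segments, truth)
    converged <- FALSE
    if (config$epochs > 0) {
      for (ep in seq_len(config$epochs)) {
        state <- run_epoch(state, config, ep)
        row <- append_truth_metrics(state$metrics, state$segments, truth)
        trace <- rbind(trace, row)
        if (state$metrics$frac_changed < config$convergence_frac) {
          converged <- TRUE
          break
        }
      }
    }
    structure(list(segments = state$segments, trace = trace,
                   clusters = state$clusters %||% NULL,
                   audit = state$audit %||% NULL,
                   embedding = state$embedding,
                   embedding_labels = state$embedding_labels,
                   mask = state$mask, config = config, converged = converged),
              class = "tasc_result")
  })
}

#' @noRd
append_truth_metrics <- function(row, segments, truth) {
  if (is.null(truth)) {
    row$iou_vs_truth <- NA_real_
    row$boundary_l1_vs_truth <- NA_real_
    return(row)
  }
  m <- match_segments(segments, truth)
  row$iou_vs_truth <- mean_iou(segments, truth, matches = m)
  row$boundary_l1_vs_truth <- if (nrow(m) > 0)
    boundary_l1(m, segments, truth) else 0
  row
}

#' @export
print.tasc_result <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<tasc_result> %d segments after epoch %d%s\n",
              nrow(x$segments), last$epoch,
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  mean cost %.4g | silhouette %.3f",
              last$mean_cost, last$silhouette))
  if (!is.na(last$iou_vs_truth))
    cat(sprintf(" | IoU vs truth %.3f | boundary L1 %g",
                last$iou_vs_truth, last$boundary_l1_vs_truth))
  cat("\n")
  invisible(x)
}

#' Plot the per-epoch metric trace
#' @param x A `tasc_result`.
#' @param ... Unused.
#' @importFrom graphics plot lines legend par
#' @export
plot.tasc_result <- function(x, ...) {
  tr <- x$trace
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(tr$epoch, tr$silhouette, type = "b", xlab = "epoch",
       ylab = "silhouette", main = "clustering quality")
  if (all(!is.na(tr$iou_vs_truth))) {
    plot(tr$epoch, tr$iou_vs_truth, type = "b", xlab = "epoch",
         ylab = "mean IoU vs truth", main = "segmentation accuracy")
  } else {
    plot(tr$epoch, tr$n_segments, type = "b", xlab = "epoch",
         ylab = "segments", main = "segment count")
  }
  invisible(x)
}
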