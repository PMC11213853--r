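#' Embedder specification (F_E)
#'
#' The embedding interface is pluggable: any object with this shape can be
#' passed where an embedder is expected. The shipped default is principal
#' component analysis on segments resampled to a common length and
#' flattened frame-by-frame (each frame's D feature values contiguous,
#' i.e. column-major order of the D x L matrix).
#'
#' @param n_components Number of components to keep; a value in (0, 1) is
#'   interpreted as a variance-explained fraction.
#' @param target_length Common length segments are resampled to before
#'   embedding; `NULL` means "decide at fit time" (the rounded mean segment
#'   length).
#' @return Object of class `tasc_embedder`.
#' @export
pca_embedder <- function(n_components = 10, target_length = NULL) {
  structure(list(name = "pca", n_components = n_components,
                 target_length = target_length),
            class = "tasc_embedder")
}

# Fit PCA on an N x P matrix of flattened sequences; returns embedding + fit.
#' @noRd
fit_pca <- function(flat, n_components) {
  n <- nrow(flat)
  fit <- prcomp(flat, center = TRUE, scale. = FALSE)
  if (n_components < 1) {
    ve <- cumsum(fit$sdev^2) / sum(fit$sdev^2)
    d <- which(ve >= n_components)[1]
  } else {
    d <- as.integer(n_components)
    if (n <= d)
      stop(sprintf(paste0("%d segments cannot support %d principal components; ",
                          "reduce `n_components`"), n, d))
  }
  d <- min(d, ncol(fit$x))
  list(embedding = fit$x[, seq_len(d), drop = FALSE], fit = fit, d = d)
}

#' @noRd
flatten_sequences <- function(seqs, target_length) {
  do.call(rbind, lapply(seqs, function(m)
    as.vector(resample_sequence(m, target_length))))
}

# Embed a list of D x L_i matrices; common resample length decided here.
#' @noRd
embed_sequences <- function(seqs, embedder, target_length = NULL) {
  if (length(seqs) < 2) stop("need at least 2 segments to embed")
  tl <- target_length %||% embedder$target_length %||%
    max(2L, round(mean(vapply(seqs, ncol, 1L))))
  flat <- flatten_sequences(seqs, tl)
  res <- fit_pca(flat, embedder$n_components)
  attr(res$embedding, "target_length") <- tl
  res$embedding
}

#' Embed segments into a low-dimensional space
#'
#' Resamples every segment to a uniform length, flattens, and fits the
#' embedder (PCA by default, refit on each call). Rows of the returned
#' matrix follow the input segment order.
#'
#' @param signal A [tasc_signal()].
#' @param segments Segment data frame.
#' @param embedder A [pca_embedder()] (or compatible spec).
#' @param target_length Override for the common resample length; defaults to
#'   the embedder's setting or the rounded mean segment length.
#' @return N x d numeric matrix with attribute `target_length`.
#' @export
embed_segments <- function(signal, segments, embedder = pca_embedder(),
                           target_length = NULL) {
  signal <- as_tasc_signal(signal)
  embed_sequences(segment_slices(signal, segments), embedder, target_length)
}

#' Clusterer specification (F_C)
#'
#' Fuzzy c-means with deterministic farthest-first center initialization:
#' the first center is the point nearest the data mean and each subsequent
#' center the point farthest from those already chosen, making the
#' clustering reproducible and invariant to row permutation without any
#' random draw. The soft memberships double as selection scores.
#'
#' @param n_clusters Number of clusters (>= 2).
#' @param fuzziness FCM fuzzifier m (> 1); default 1.5 (the common 2.0
#'   drives center collapse on weakly separated embeddings: all centers
#'   migrate to the grand mean and the hard labels degenerate).
#' @param seed Kept for interface compatibility with stochastic clusterers;
#'   the default initialization uses no randomness.
#' @param max_iter Iteration cap.
#' @return Object of class `tasc_clusterer`.
#' @export
fcm_clusterer <- function(n_clusters, fuzziness = 1.5, seed = 1L,
                          max_iter = 1000) {
  if (n_clusters < 2) stop("`n_clusters` must be >= 2")
  if (fuzziness <= 1) stop("`fuzziness` must be > 1")
  structure(list(name = "fcm", n_clusters = as.integer(n_clusters),
                 fuzziness = fuzziness, seed = as.integer(seed),
                 max_iter = as.integer(max_iter)),
            class = "tasc_clusterer")
}

# Deterministic, permutation-invariant maximin center selection.
#' @noRd
farthest_first_centers <- function(x, k) {
  mu <- colMeans(x)
  d0 <- colSums((t(x) - mu)^2)
  idx <- which.min(d0)
  mind <- colSums((t(x) - x[idx, ])^2)
  for (j in seq_len(k - 1)) {
    nxt <- which.max(mind)
    idx <- c(idx, nxt)
    mind <- pmin(mind, colSums((t(x) - x[nxt, ])^2))
  }
  x[idx, , drop = FALSE]
}

#' Cluster embedded segments
#'
#' Runs the clusterer on the embedding rows and returns hard labels (argmax
#' membership) together with the soft membership matrix (rows sum to 1).
#'
#' @param embeddings N x d numeric matrix.
#' @param clusterer A [fcm_clusterer()].
#' @return List with integer `labels` (1..K) and N x K `memberships`.
#' @export
cluster_segments <- function(embeddings, clusterer) {
  embeddings <- as.matrix(embeddings)
  k <- clusterer$n_clusters
  if (nrow(embeddings) < k)
    stop("fewer segments than clusters")
  if (all(apply(embeddings, 2, function(col) diff(range(col)) == 0)))
    stop("degenerate embeddings: all points identical, clustering undefined")
  centers <- farthest_first_centers(embeddings, k)
  fit <- local_seed(clusterer$seed,
                    e1071::cmeans(embeddings, centers = centers,
                                  iter.max = clusterer$max_iter,
                                  m = clusterer$fuzziness))
  memberships <- unname(fit$membership)
  labels <- max.col(memberships, ties.method = "first")
  list(labels = labels, memberships = memberships)
}

#' Choose a cluster count by the silhouette method
#'
#' Runs the clusterer for each candidate K and returns the one maximizing
#' the mean silhouette width; ties break toward the smaller K.
#'
#' @param embeddings N x d numeric matrix.
#' @param k_range Integer vector of candidate cluster counts (within
#'   `[2, N - 1]`).
#' @param clusterer A [fcm_clusterer()]; its `n_clusters` field is ignored.
#' @return The selected integer K.
#' @export
select_cluster_count <- function(embeddings, k_range,
                                 clusterer = fcm_clusterer(2)) {
  embeddings <- as.matrix(embeddings)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("`k_range` is empty")
  if (min(k_range) < 2 || max(k_range) > nrow(embeddings) - 1)
    stop("`k_range` must lie within [2, N - 1]")
  dmat <- dist(embeddings)
  if (all(dmat == 0))
    stop("identical points: silhouette undefined")
  best_k <- NA_integer_; best_s <- -Inf
  for (k in k_range) {
    cl <- cluster_segments(embeddings, modifyList(clusterer, list(n_clusters = k)))
    s <- mean(cluster::silhouette(cl$labels, dmat)[, "sil_width"])
    if (s > best_s) { best_s <- s; best_k <- k }
  }
  best_k
}

#' Thin out temporally and latently redundant segments
#'
#' Greedy pass in input order: a segment is dropped when it overlaps an
#' already-retained segment by more than `max_overlap_fraction` of its own
#' length AND its embedding lies within `latent_radius` of that retained
#' segment's embedding. Reduces the temporal dependency of densely strided
#' initial segmentations. The first segment is always retained.
#'
#' @param segments Segment data frame.
#' @param embeddings Matching N x d embedding matrix.
#' @param max_overlap_fraction Overlap tolerance (default 0.5).
#' @param latent_radius Latent closeness threshold; defaults to the median
#'   nearest-neighbor distance among the embeddings.
#' @return The retained subset of `segments`.
#' @export
spatiotemporal_dilution <- function(segments, embeddings,
                                    max_overlap_fraction = 0.5,
                                    latent_radius = NULL) {
  n <- nrow(segments)
  if (n <= 1) return(segments)
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != n) stop("embeddings must align with segments")
  if (is.null(latent_radius)) {
    dm <- as.matrix(dist(embeddings))
    diag(dm) <- Inf
    latent_radius <- median(apply(dm, 1, min))
  }
  keep <- 1L
  for (i in 2:n) {
    len_i <- segments$end[i] - segments$start[i]
    ov <- pmax(0, pmin(segments$end[i], segments$end[keep]) -
                    pmax(segments$start[i], segments$start[keep]))
    close <- ov / len_i > max_overlap_fraction
    if (any(close)) {
      dlat <- sqrt(colSums((t(embeddings[keep[close], , drop = FALSE]) -
                              embeddings[i, ])^2))
      if (any(dlat <= latent_radius)) next
    }
    keep <- c(keep, i)
  }
  segments[keep, , drop = FALSE]
}
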