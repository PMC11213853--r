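#' Generate a library of synthetic multichannel motifs
#'
#' Stands in for manually curated motif templates: each motif is a smooth,
#' distinguishable multichannel sequence built per feature from 1-3 random
#' low-frequency components (sinusoids and Gaussian bumps). Motifs are
#' regenerated until every pair is at least `min_separation` apart in
#' weighted Euclidean distance. Fully deterministic per seed; user-supplied
#' motif matrices are accepted verbatim.
#'
#' @param n_motifs Number of motifs (>= 2); default 5.
#' @param length_range Inclusive frame-length range; default 60-90 frames
#'   (sub-second motifs at 120 fps).
#' @param n_features Channels per motif; default 5.
#' @param seed RNG seed.
#' @param min_separation Minimum pairwise weighted distance.
#' @param motifs Optional list of feature x frame matrices to use as-is.
#' @return Object of class `motif_library`: list with `motifs` (list of
#'   D x L matrices), `labels` (0-based), `seed`.
#' @export
make_motif_library <- function(n_motifs = 5, length_range = c(60, 90),
                               n_features = 5, seed = 1L,
                               min_separation = 1, motifs = NULL) {
  if (!is.null(motifs)) {
    return(structure(list(motifs = lapply(motifs, as.matrix),
                          labels = seq_along(motifs) - 1L, seed = NA_integer_),
                     class = "motif_library"))
  }
  if (n_motifs < 2) stop("`n_motifs` must be >= 2")
  if (length_range[1] < 4) stop("motifs shorter than 4 frames are not supported")
  local_seed(seed, {
    out <- vector("list", n_motifs)
    for (i in seq_len(n_motifs)) {
      for (try in 1:50) {
        m <- random_motif(length_range, n_features)
        dists <- if (i == 1) Inf else
          vapply(out[seq_len(i - 1)], weighted_euclidean, numeric(1), y = m)
        if (min(dists) >= min_separation) break
      }
      out[[i]] <- m
    }
    structure(list(motifs = out, labels = seq_len(n_motifs) - 1L,
                   seed = as.integer(seed)),
              class = "motif_library")
  })
}

#' @noRd
random_motif <- function(length_range, n_features) {
  len <- sample(length_range[1]:length_range[2], 1)
  t01 <- seq(0, 1, length.out = len)
  m <- matrix(0, n_features, len)
  for (d in seq_len(n_features)) {
    for (comp in seq_len(sample(1:3, 1))) {
      if (runif(1) < 0.5) {
        a <- runif(1, 0.4, 1.5); f <- runif(1, 0.5, 2); ph <- runif(1, 0, 2 * pi)
        m[d, ] <- m[d, ] + a * sin(2 * pi * f * t01 + ph)
      } else {
        a <- runif(1, 0.4, 1.5) * sample(c(-1, 1), 1)
        ctr <- runif(1, 0.2, 0.8); wd <- runif(1, 0.05, 0.2)
        m[d, ] <- m[d, ] + a * exp(-(t01 - ctr)^2 / (2 * wd^2))
      }
    }
  }
  m
}

#' @export
print.motif_library <- function(x, ...) {
  cat(sprintf("<motif_library> %d motifs, %d features, lengths %s\n",
              length(x$motifs), nrow(x$motifs[[1]]),
              paste(vapply(x$motifs, ncol, 1L), collapse = ",")))
  invisible(x)
}

#' Randomly warped instance of a motif
#'
#' Draws a shift `tau_w ~ U(-0.1, 0.1)` and slope `s_w ~ U(0.8, 1.2)` (the
#' generation-scale warp distribution) and applies [warp_sequence()]. The
#' output length is `round(len / s_w)`, so slower executions come out
#' longer; the draw is recorded so the variant can be reconstructed exactly.
#'
#' @param motif Features x frames matrix.
#' @param tau_range,s_range Uniform draw boxes.
#' @param params Optional fixed `c(tau_w, s_w)` instead of a draw.
#' @return List with `variant` (matrix), `tau_w`, `s_w`.
#' @export
warp_motif <- function(motif, tau_range = c(-0.1, 0.1), s_range = c(0.8, 1.2),
                       params = NULL) {
  if (is.null(params)) {
    tau <- runif(1, tau_range[1], tau_range[2])
    s <- runif(1, s_range[1], s_range[2])
  } else {
    tau <- params[[1]]; s <- params[[2]]
  }
  len <- ncol(motif)
  out_len <- max(2L, as.integer(round(len / s)))
  list(variant = warp_sequence(motif, c(tau, s), out_len, domain_length = len),
       tau_w = tau, s_w = s)
}

#' Assemble a ground-truthed semi-synthetic signal
#'
#' Replicates the standard validation protocol: every motif is instantiated
#' `n_variants_per_motif` times with independent random linear warps, the
#' instances are laid down in seeded random order on a constant baseline
#' equal to the per-feature mean across all motifs, separated by baseline
#' gaps of random length; the signal is min-max normalized to `[0, 1]` and
#' independent Gaussian noise is added. True boundaries, labels and warp
#' draws are retained.
#'
#' @param library A [make_motif_library()].
#' @param n_variants_per_motif Instances per motif; default 20.
#' @param noise_sigma White-noise standard deviation; default 0.01.
#' @param seed RNG seed for draws, order and noise.
#' @param gap_range Inclusive uniform range of inter-instance baseline gap
#'   lengths in frames; default 30-90 (use `c(0, 0)` for back-to-back).
#' @param frame_rate Frames per second recorded on the signal; default 120.
#' @return Object of class `tasc_dataset`: `signal` ([tasc_signal()]),
#'   `truth` (labeled segment data frame), `warp_record` (per-instance
#'   draws), `baseline`, `seed`.
#' @export
assemble_signal <- function(library, n_variants_per_motif = 20,
                            noise_sigma = 0.01, seed = 1L,
                            gap_range = c(30, 90), frame_rate = 120) {
  if (n_variants_per_motif < 1) stop("`n_variants_per_motif` must be >= 1")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  D <- nrow(library$motifs[[1]])
  local_seed(seed, {
    inst <- list()
    for (k in seq_along(library$motifs))
      for (r in seq_len(n_variants_per_motif)) {
        w <- warp_motif(library$motifs[[k]])
        inst[[length(inst) + 1]] <- list(label = library$labels[k],
                                         variant = w$variant,
                                         tau_w = w$tau_w, s_w = w$s_w)
      }
    inst <- inst[sample(length(inst))]
    n <- length(inst)
    gaps <- if (gap_range[2] > 0)
      sample(gap_range[1]:gap_range[2], n + 1, replace = TRUE) else rep(0L, n + 1)
    baseline <- rowMeans(do.call(cbind, library$motifs))
    T_ <- sum(vapply(inst, function(i) ncol(i$variant), 1L)) + sum(gaps)
    values <- matrix(baseline, D, T_)
    pos <- gaps[1]
    truth <- list(); rec <- list()
    for (i in seq_len(n)) {
      len <- ncol(inst[[i]]$variant)
      values[, (pos + 1):(pos + len)] <- inst[[i]]$variant
      truth[[i]] <- data.frame(start = pos, end = pos + len,
                               label = inst[[i]]$label)
      rec[[i]] <- data.frame(instance = i, label = inst[[i]]$label,
                             tau_w = inst[[i]]$tau_w, s_w = inst[[i]]$s_w,
                             start = pos, end = pos + len)
      pos <- pos + len + gaps[i + 1]
    }
    truth <- do.call(rbind, truth)
    sig <- normalize_signal(tasc_signal(values, frame_rate = frame_rate))
    if (noise_sigma > 0)
      sig$values <- sig$values + matrix(rnorm(D * T_, 0, noise_sigma), D, T_)
    structure(list(signal = sig,
                   truth = new_segments(truth$start, truth$end,
                                        label = truth$label),
                   warp_record = do.call(rbind, rec),
                   baseline = baseline, seed = as.integer(seed),
                   noise_sigma = noise_sigma, gap_range = gap_range),
              class = "tasc_dataset")
  })
}

#' @export
print.tasc_dataset <- function(x, ...) {
  cat(sprintf("<tasc_dataset> %d features x %d frames, %d true segments (%d classes), noise sd %g\n",
              nrow(x$signal$values), ncol(x$signal$values), nrow(x$truth),
              length(unique(x$truth$label)), x$noise_sigma))
  invisible(x)
}

#' Write / read a synthetic dataset as plain-text files
#'
#' `signal.csv` (frames x features), `truth.csv` (segment CSV),
#' `warps.csv`, and `manifest.json` carrying seeds and parameters --
#' sufficient for bit-exact regeneration.
#'
#' @param dataset A `tasc_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_csv(dataset$signal, file.path(dir, "signal.csv"))
  write_segments_csv(dataset$truth, file.path(dir, "truth.csv"))
  write.csv(dataset$warp_record, file.path(dir, "warps.csv"), row.names = FALSE)
  manifest <- list(seed = dataset$seed, noise_sigma = dataset$noise_sigma,
                   gap_range = dataset$gap_range,
                   frame_rate = dataset$signal$frame_rate,
                   n_features = nrow(dataset$signal$values),
                   n_frames = ncol(dataset$signal$values),
                   n_truth = nrow(dataset$truth),
                   package_version = as.character(packageVersion("tasc")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  sig <- read_signal_csv(file.path(dir, "signal.csv"),
                         frame_rate = manifest$frame_rate)
  truth <- read_segments_csv(file.path(dir, "truth.csv"),
                             n_frames = ncol(sig$values))
  structure(list(signal = sig, truth = truth,
                 warp_record = read.csv(file.path(dir, "warps.csv")),
                 baseline = NULL, seed = manifest$seed,
                 noise_sigma = manifest$noise_sigma,
                 gap_range = unlist(manifest$gap_range)),
            class = "tasc_dataset")
}
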