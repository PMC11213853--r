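# Shared fixtures, all generated in code.

# Well-separated Gaussian blobs in d dimensions.
make_blobs <- function(n_per = 20, k = 3, d = 4, sep = 10, spread = 0.5,
                       seed = 7) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * d, sd = spread), n_per, d), 2, centers[i, ], "+")))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# Smooth random multichannel template for alignment tests.
random_template <- function(len = 80, d = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t01 <- seq(0, 1, length.out = len)
  m <- matrix(0, d, len)
  for (i in seq_len(d))
    m[i, ] <- sin(2 * pi * runif(1, 0.5, 2) * t01 + runif(1, 0, 2 * pi)) +
      exp(-(t01 - runif(1, 0.2, 0.8))^2 / (2 * runif(1, 0.05, 0.15)^2))
  m
}

# Exhaustive-enumeration optimum for weighted interval scheduling (n <= ~15).
brute_force_wis <- function(start, end, score) {
  n <- length(start)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1) {
      o <- order(start[idx])
      ii <- idx[o]
      if (any(start[ii][-1] < end[ii][-length(ii)])) next
    }
    best <- max(best, sum(score[idx]))
  }
  best
}

# Small fast semi-synthetic dataset for pipeline tests.
small_dataset <- function(n_variants = 4, noise = 0.01, seed = 11,
                          lib_seed = 5) {
  lib <- make_motif_library(n_motifs = 3, length_range = c(30, 45),
                            n_features = 3, seed = lib_seed)
  assemble_signal(lib, n_variants_per_motif = n_variants,
                  noise_sigma = noise, seed = seed, gap_range = c(20, 40))
}

# Matching reduced-size configuration (windows sized to the motif scale).
small_config <- function(epochs = 2, seed = 1, ...) {
  args <- list(window = 40, n_clusters = 3, n_components = 5,
               M = c(-6, 6), L = function(n) c(-n, 6),
               alpha = 10^seq(0.5, -1, length.out = max(epochs, 1)),
               gamma = 4, epochs = epochs, seed = seed)
  do.call(tasc_config, utils::modifyList(args, list(...)))
}
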