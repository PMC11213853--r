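test_that("motif libraries are reproducible, distinct and validated", {
  lib <- make_motif_library(n_motifs = 3, length_range = c(30, 45),
                            n_features = 2, seed = 9)
  lib2 <- make_motif_library(n_motifs = 3, length_range = c(30, 45),
                             n_features = 2, seed = 9)
  expect_identical(lib, lib2)
  lens <- vapply(lib$motifs, ncol, 1L)
  expect_true(all(lens >= 30 & lens <= 45))
  dists <- outer(1:3, 1:3, Vectorize(function(i, j)
    weighted_euclidean(lib$motifs[[i]], lib$motifs[[j]])))
  expect_gt(min(dists[upper.tri(dists)]), 0)
  expect_error(make_motif_library(length_range = c(2, 3)), "4 frames")
  # user-supplied motifs pass through verbatim
  own <- list(matrix(1:12, 2, 6), matrix(0, 2, 8))
  expect_identical(make_motif_library(motifs = own)$motifs, own)
})

test_that("warp draws stay in the stated boxes and set the length rule", {
  motif <- random_template(90, 2, seed = 1)
  set.seed(2)
  for (i in 1:50) {
    w <- warp_motif(motif)
    expect_gte(w$tau_w, -0.1); expect_lte(w$tau_w, 0.1)
    expect_gte(w$s_w, 0.8); expect_lte(w$s_w, 1.2)
    expect_equal(ncol(w$variant), round(90 / w$s_w))
  }
  fixed <- warp_motif(motif, params = c(0, 0.8))
  expect_true(ncol(fixed$variant) %in% c(112, 113))  # round(90 / 0.8)
  ident <- warp_motif(motif, params = c(0, 1))
  expect_equal(ident$variant, motif, tolerance = 1e-12)
})

test_that("assembled datasets tile exactly and carry coherent ground truth", {
  ds <- small_dataset(n_variants = 3, noise = 0.01, seed = 21)
  expect_equal(nrow(ds$truth), 3 * 3)
  validate_segments(ds$truth, n_frames = ncol(ds$signal$values),
                    require_nonoverlap = TRUE)
  expect_true(all(diff(ds$truth$start) > 0))  # sorted
  # truth frames + gap frames account for every frame
  seg_frames <- sum(ds$truth$end - ds$truth$start)
  gap_frames <- ncol(ds$signal$values) - seg_frames
  expect_gte(gap_frames, 4 * 20)  # >= (n+1) gaps of at least the minimum
  expect_true(all(ds$signal$values >= -0.1 & ds$signal$values <= 1.1))
  # reproducibility from the seed pair
  ds2 <- small_dataset(n_variants = 3, noise = 0.01, seed = 21)
  expect_identical(ds$signal$values, ds2$signal$values)
  expect_identical(ds$truth, ds2$truth)
})

test_that("recorded warps reconstruct every noiseless variant exactly", {
  lib <- make_motif_library(n_motifs = 2, length_range = c(20, 30),
                            n_features = 2, seed = 4)
  ds <- assemble_signal(lib, n_variants_per_motif = 2, noise_sigma = 0,
                        seed = 5, gap_range = c(10, 15))
  # rebuild the pre-normalization signal from baseline + recorded warps,
  # then apply the same per-feature min-max map and compare slices
  D <- 2
  T_ <- ncol(ds$signal$values)
  raw <- matrix(ds$baseline, D, T_)
  for (i in seq_len(nrow(ds$warp_record))) {
    r <- ds$warp_record[i, ]
    motif <- lib$motifs[[r$label + 1]]
    v <- warp_sequence(motif, c(r$tau_w, r$s_w),
                       r$end - r$start, ncol(motif))
    raw[, (r$start + 1):r$end] <- v
  }
  lo <- apply(raw, 1, min); hi <- apply(raw, 1, max)
  expect_equal((raw - lo) / (hi - lo), ds$signal$values, tolerance = 1e-12)
})

test_that("datasets round-trip through the plain-text file set", {
  ds <- small_dataset(n_variants = 2, seed = 31)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("signal.csv", "truth.csv",
                                               "warps.csv", "manifest.json")))))
  back <- read_dataset(dir)
  expect_equal(back$signal$values, ds$signal$values, tolerance = 1e-12)
  expect_equal(back$truth, ds$truth)
  expect_equal(back$noise_sigma, ds$noise_sigma)
})
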