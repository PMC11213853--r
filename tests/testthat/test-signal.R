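test_that("normalization is an exact per-feature min-max map", {
  sig <- tasc_signal(matrix(c(2, 4, 6,
                              5, 5, 5,
                              0, 1, 0.25), 3, 3, byrow = TRUE))
  norm <- normalize_signal(sig)
  expect_equal(norm$values[1, ], c(0, 0.5, 1))
  expect_equal(norm$values[2, ], c(0, 0, 0))        # constant feature rule
  expect_equal(norm$values[3, ], c(0, 1, 0.25))     # already normalized
  expect_equal(normalize_signal(norm)$values, norm$values)  # idempotent
})

test_that("non-finite input is rejected with feature and frame named", {
  m <- matrix(1, 2, 4)
  m[2, 3] <- NaN
  expect_error(tasc_signal(m), "feature 2 at frame 3")
})

test_that("activity detection finds a single high-motion block", {
  set.seed(3)
  T_ <- 600
  v <- matrix(0.5, 2, T_)
  block <- 201:400
  v[, block] <- 0.5 + 0.4 * sin(seq(0, 40, length.out = length(block))) %o% c(1, 1)
  sig <- normalize_signal(tasc_signal(v + matrix(rnorm(2 * T_, 0, 1e-4), 2),
                                      frame_rate = 100))
  mask <- detect_activity_periods(sig, cutoff_hz = 2, threshold_quantile = 0.7,
                                  min_period_frames = 20)
  runs <- rle(mask$active)
  active_runs <- sum(runs$values)
  expect_equal(active_runs, 1)
  # run extent matches the block up to the filter's edge width
  on <- range(which(mask$active))
  expect_lt(abs(on[1] - min(block)), 50)
  expect_lt(abs(on[2] - max(block)), 50)
  expect_equal(mask$active, mask$smoothed_energy >= mask$threshold_used)
})

test_that("motionless signals are fully inactive and short runs are culled", {
  flat <- tasc_signal(matrix(0.3, 2, 50), frame_rate = 30)
  mask <- detect_activity_periods(flat)
  expect_false(any(mask$active))
  # a min_period longer than any active run suppresses the mask entirely
  set.seed(1)
  sig <- normalize_signal(tasc_signal(matrix(runif(100), 2, 50), frame_rate = 30))
  mask2 <- detect_activity_periods(sig, min_period_frames = 51)
  expect_false(any(mask2$active))
  expect_error(detect_activity_periods(tasc_signal(matrix(1, 1, 2))), "too short")
})

test_that("activity detection ignores per-feature affine rescaling", {
  set.seed(9)
  v <- matrix(cumsum(rnorm(3 * 200)), 3, 200, byrow = TRUE)
  a <- normalize_signal(tasc_signal(v, frame_rate = 50))
  b <- normalize_signal(tasc_signal(v * c(10, -2, 0.5) + c(3, -1, 100),
                                    frame_rate = 50))
  ma <- detect_activity_periods(a)
  mb <- detect_activity_periods(b)
  expect_equal(ma$active, mb$active)
})

test_that("segment validity is the inclusive 90% active-fraction rule", {
  active <- rep(FALSE, 30)
  active[1:19] <- TRUE
  mask <- structure(list(active = active, threshold_used = 0,
                         smoothed_energy = as.numeric(active)),
                    class = "tasc_activity")
  segs <- new_segments(start = c(0, 5, 9, 10), end = c(10, 15, 19, 20))
  # active frames inside: 10/10, 10/10, 10/10 -> kept; [10,20): 9/10 kept too
  kept <- filter_valid_segments(segs, mask)
  expect_equal(kept$start, c(0, 5, 9, 10))
  segs2 <- new_segments(start = 12, end = 22)  # 7 active of 10 -> dropped
  expect_equal(nrow(filter_valid_segments(segs2, mask)), 0)
  segs3 <- new_segments(start = 11, end = 21)  # 8 active of 10 -> dropped
  expect_equal(nrow(filter_valid_segments(segs3, mask)), 0)
  # all-active mask keeps everything; all-inactive keeps nothing
  all_on <- structure(list(active = rep(TRUE, 30)), class = "tasc_activity")
  all_off <- structure(list(active = rep(FALSE, 30)), class = "tasc_activity")
  expect_equal(filter_valid_segments(segs, all_on), segs)
  expect_equal(nrow(filter_valid_segments(segs, all_off)), 0)
})

test_that("signal CSV round-trips frames-by-features with names", {
  sig <- tasc_signal(matrix(runif(12), 3, 4), frame_rate = 60,
                     feature_names = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, path)
  back <- read_signal_csv(path, frame_rate = 60)
  expect_equal(back$values, sig$values)
  expect_equal(back$feature_names, sig$feature_names)
})
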