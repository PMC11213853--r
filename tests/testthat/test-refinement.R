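test_that("the gamma rule removes exactly the distant member", {
  set.seed(8)
  base <- random_template(30, 2)
  members <- c(lapply(1:9, function(i) base + rnorm(60, sd = 1e-3)),
               list(base + 5))
  out <- remove_outliers(members, gamma = 1)
  expect_equal(out$removed, 10L)
  expect_equal(out$kept, 1:9)
  # statistics are those computed before removal
  dmat <- sapply(members, function(a) sapply(members, weighted_euclidean, y = a))
  di <- rowSums(dmat) / 9
  expect_equal(out$mean_distance, mean(di))
  expect_equal(out$distance_std, sd(di))
  # gamma -> infinity removes nothing
  expect_length(remove_outliers(members, gamma = 1e9)$removed, 0)
  # degenerate small cluster passes through flagged
  one <- remove_outliers(members[1], gamma = 1)
  expect_true(one$degenerate)
  expect_equal(one$kept, 1L)
})

test_that("centroids are element-wise summaries or an actual member", {
  m1 <- matrix(1, 2, 6); m2 <- matrix(2, 2, 6); m3 <- matrix(10, 2, 6)
  expect_equal(compute_centroid(list(m1), existing = FALSE), m1)
  med <- compute_centroid(list(m1, m2, m3), method = "median", existing = FALSE)
  expect_equal(med, matrix(2, 2, 6))
  avg <- compute_centroid(list(m1, m2, m3), method = "mean", existing = FALSE)
  expect_equal(avg, matrix(13 / 3, 2, 6))
  ex <- compute_centroid(list(m1, m2, m3), method = "mean", existing = TRUE)
  expect_true(any(vapply(list(m1, m2, m3), identical, logical(1), y = ex)))
  expect_error(compute_centroid(list()), "empty")
})

test_that("variant grids enumerate the inclusive offset-by-length box", {
  seg <- new_segments(30, 100)
  g <- generate_variants(seg, M = c(-10, 10), L = c(-1, 10), n_frames = 1000)
  expect_equal(nrow(g), 21 * 12)
  expect_true(all(g$valid))
  single <- generate_variants(seg, M = c(0, 0), L = c(0, 0), n_frames = 1000)
  expect_equal(nrow(single), 1)
  expect_equal(c(single$start, single$end), c(30, 100))
  # clipping at the signal start marks variants invalid
  edge <- generate_variants(new_segments(5, 40), M = c(-10, 10), L = c(0, 0),
                            n_frames = 45)
  expect_equal(sum(!edge$valid), 5 + 5)  # m < -5 clips start; m > 5 clips end
  expect_true(all(edge$end[edge$valid] <= 45 & edge$start[edge$valid] >= 0))
})

test_that("cost-to-score conversion is per-cluster and scale invariant", {
  expect_equal(costs_to_scores(c(0.2, 0.4), c(1, 1)), c(0.5, 0))
  expect_equal(costs_to_scores(c(0, 0, 0), c(1, 1, 1)), c(1, 1, 1))
  s1 <- costs_to_scores(c(0.2, 0.4, 3, 9), c(1, 1, 2, 2))
  s2 <- costs_to_scores(c(0.2, 0.4, 30, 90), c(1, 1, 2, 2))
  expect_equal(s1, s2)  # rescaling one cluster's costs changes nothing
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(costs_to_scores(c(0.5, NA), c(1, 1))[2], -Inf)
})

test_that("non-overlapping selection is the exhaustive optimum", {
  # worked example: A and C beat the higher-overlap alternatives
  st <- c(0, 5, 12); en <- c(10, 15, 20); sc <- c(1, 1, 0.8)
  sel <- select_nonoverlapping(st, en, sc)
  expect_equal(sort(sel), c(1, 3))
  expect_equal(sum(sc[sel]), 1.8)
  # two overlapping intervals: higher score wins
  expect_equal(select_nonoverlapping(c(0, 5), c(10, 15), c(0.9, 0.5)), 1)
  # non-overlapping input is kept in full
  expect_equal(sort(select_nonoverlapping(c(0, 10, 20), c(10, 20, 30),
                                          c(0.1, 0.2, 0.3))), 1:3)
  expect_equal(select_nonoverlapping(integer(0), integer(0), numeric(0)),
               integer(0))
  # randomized equivalence with subset enumeration
  set.seed(31)
  for (r in 1:60) {
    n <- sample(1:10, 1)
    st <- sample(0:40, n, TRUE)
    en <- st + sample(2:12, n, TRUE)
    sc <- round(runif(n), 3)
    sel <- select_nonoverlapping(st, en, sc)
    expect_equal(sum(sc[sel]), brute_force_wis(st, en, sc), tolerance = 1e-9)
    if (length(sel) > 1) {
      o <- order(st[sel])
      expect_true(all(st[sel][o][-1] >= en[sel][o][-length(sel)]))
    }
  }
})

test_that("variant scoring ranks the true motif above noise and skips invalid", {
  set.seed(77)
  motif <- random_template(40, 2)
  T_ <- 200
  v <- matrix(rnorm(2 * T_, sd = 0.05), 2, T_)
  v[, 81:120] <- motif
  sig <- tasc_signal(v)
  seg <- new_segments(80, 120)
  g <- generate_variants(seg, M = c(-60, 0), L = c(0, 0), n_frames = T_)
  g <- score_variants(g, sig, motif, alpha = 0)
  expect_true(all(is.na(g$cost) == !g$valid))
  # the m = 0 variant contains the motif exactly and must win the grid
  expect_equal(g$m[which.min(g$cost)], 0)
  # a far-shifted pure-noise variant costs strictly more
  expect_gt(g$cost[g$m == -60], g$cost[g$m == 0])
})

test_that("gap reassignment recovers a planted centroid copy and skips noise", {
  set.seed(91)
  centroid <- random_template(30, 2)
  T_ <- 200
  v <- matrix(rnorm(2 * T_, sd = 3), 2, T_)   # loud noise far from centroid
  v[, 101:130] <- centroid                    # planted copy in the gap
  sig <- tasc_signal(v)
  selected <- new_segments(start = c(0, 160), end = c(30, 190),
                           label = c(1, 1), score = 1)
  clusters <- list(list(label = 1, centroid = centroid, mean_distance = 2))
  out <- reassign_gaps(selected, sig, clusters, mean_segment_length = 30,
                       stride = 1)
  new <- out[!(out$start %in% selected$start), ]
  expect_equal(nrow(new), 1)
  expect_equal(new$label, 1)
  expect_lte(abs(new$start - 100), 1)
  validate_segments(out, n_frames = T_, require_nonoverlap = TRUE)
  # without a planted copy nothing beats the cluster's mean distance
  v2 <- matrix(rnorm(2 * T_, sd = 3), 2, T_)
  out2 <- reassign_gaps(selected, tasc_signal(v2), clusters,
                        mean_segment_length = 30, stride = 5)
  expect_equal(nrow(out2), nrow(selected))
  # gaps shorter than the mean segment length are never scanned
  tight <- new_segments(start = c(0, 40), end = c(30, 70), label = c(1, 1))
  out3 <- reassign_gaps(tight, tasc_signal(v[, 1:80, drop = FALSE]), clusters,
                        mean_segment_length = 30, stride = 5)
  expect_equal(nrow(out3), 2)
})
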