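test_that("interval IoU has its closed-form values and symmetry", {
  expect_equal(interval_iou(c(0, 10), c(0, 10)), 1)
  expect_equal(interval_iou(c(0, 10), c(5, 15)), 5 / 15)
  expect_equal(interval_iou(c(0, 10), c(20, 30)), 0)
  expect_equal(interval_iou(c(3, 9), c(5, 20)), interval_iou(c(5, 20), c(3, 9)))
  expect_equal(interval_iou(new_segments(0, 10), new_segments(5, 15)), 1 / 3)
})

test_that("correspondence matching is one-to-one with the half-duration rule", {
  truth <- new_segments(start = c(0, 50, 100), end = c(30, 80, 140),
                        label = c(0, 1, 2))
  # perfect predictions: all matched at IoU 1
  m <- match_segments(truth, truth)
  expect_equal(nrow(m), 3)
  expect_equal(m$iou, rep(1, 3))
  # shifted by more than half the truth duration: inadmissible
  # [16,46) vs [0,30): intersection 14 < 15 frames -> inadmissible;
  # [100,130) vs [100,140): intersection 30 >= 20 -> admissible
  shifted <- new_segments(start = c(16, 100), end = c(46, 130), label = c(0, 1))
  m2 <- match_segments(shifted, truth)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$truth, 3)
  far <- new_segments(start = 16, end = 46)
  expect_equal(nrow(match_segments(far, new_segments(0, 30))), 0)
  # two predictions over one truth: only the higher-IoU one matches
  two <- new_segments(start = c(0, 4), end = c(30, 34))
  m3 <- match_segments(two, new_segments(0, 30))
  expect_equal(nrow(m3), 1)
  expect_equal(m3$pred, 1)
  # no segment is used twice and size is bounded
  expect_lte(nrow(match_segments(two, truth)), min(nrow(two), nrow(truth)))
})

test_that("boundary L1 sums per-match start and end offsets", {
  truth <- new_segments(start = c(0, 50), end = c(30, 80), label = c(0, 1))
  pred <- new_segments(start = c(2, 52), end = c(32, 82))
  m <- match_segments(pred, truth)
  expect_equal(boundary_l1(m, pred, truth), 2 * 2 * 2)
  expect_equal(boundary_l1(m[1, ], pred, truth), 4)
  exact <- match_segments(truth, truth)
  expect_equal(boundary_l1(exact, truth, truth), 0)
  expect_warning(
    empty <- boundary_l1(match_segments(new_segments(200, 230), truth),
                         new_segments(200, 230), truth),
    "empty")
  expect_equal(empty, 0)
})

test_that("metrics are invariant to a common frame offset", {
  truth <- new_segments(start = c(0, 50), end = c(30, 80), label = c(0, 1))
  pred <- new_segments(start = c(3, 47), end = c(28, 85), label = c(1, 2))
  shift <- function(s, k) new_segments(s$start + k, s$end + k, label = s$label)
  for (k in c(0, 17, 400)) {
    expect_equal(mean_iou(shift(pred, k), shift(truth, k)),
                 mean_iou(pred, truth))
    m0 <- match_segments(pred, truth)
    mk <- match_segments(shift(pred, k), shift(truth, k))
    expect_equal(boundary_l1(mk, shift(pred, k), shift(truth, k)),
                 boundary_l1(m0, pred, truth))
  }
})

test_that("confusion matrix resolves label permutations; recall is exact", {
  truth <- new_segments(start = c(0, 50, 100, 150), end = c(30, 80, 140, 180),
                        label = c(0, 1, 0, 1))
  perfect <- new_segments(start = truth$start, end = truth$end,
                          label = c(2, 1, 2, 1))  # permuted cluster ids
  cr <- confusion_and_recall(perfect, truth)
  expect_equal(cr$recall, 1)
  expect_equal(sum(cr$confusion), 1)  # normalized by number of true segments
  expect_equal(unname(cr$confusion["unmatched", ]), rep(0, 3))
  # no matches: all mass in the unmatched row, recall 0
  none <- new_segments(start = 300, end = 330, label = 1)
  cr0 <- confusion_and_recall(none, truth)
  expect_equal(cr0$recall, 0)
  expect_equal(sum(cr0$confusion["unmatched", ]), 1)
})

test_that("the assignment solver maximizes agreement (vs permutations)", {
  set.seed(12)
  for (r in 1:10) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 4), k, k)
    got <- tasc:::solve_assignment(m)
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- max(vapply(perms(seq_len(k)), function(p)
      sum(m[cbind(seq_len(k), p)]), numeric(1)))
    expect_equal(sum(m[cbind(seq_len(k), got)]), best)
  }
})

test_that("clustering indices behave on blobs and random labels", {
  blobs <- make_blobs(n_per = 20, k = 2, sep = 50, spread = 0.5, seed = 3)
  idx <- clustering_indices(blobs$x, blobs$labels)
  expect_gt(idx$silhouette, 0.95)
  set.seed(4)
  rand <- clustering_indices(blobs$x[1:20, ], sample(1:2, 20, TRUE))
  expect_lt(abs(rand$silhouette), 0.35)
  # CH grows with between-cluster separation at fixed spread
  near <- make_blobs(n_per = 20, k = 2, sep = 2, spread = 0.5, seed = 3)
  expect_gt(idx$calinski_harabasz,
            clustering_indices(near$x, near$labels)$calinski_harabasz)
  expect_error(clustering_indices(blobs$x, rep(1, 40)), "2 clusters")
})
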