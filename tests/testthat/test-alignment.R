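test_that("distance weights are a raised Hamming window with unit tail", {
  w <- build_weights(5, 5)
  expect_equal(w$weights, 1 + 0.54 - 0.46 * cos(2 * pi * 0:4 / 4))
  expect_equal(which.max(w$weights), 3)  # center peak, odd minlen
  w2 <- build_weights(3, 7)
  expect_equal(length(w2$weights), 7)
  expect_equal(w2$weights[4:7], rep(1, 4))  # baseline-1 padded tail
  expect_true(all(w2$weights >= 1))
})

test_that("weighted Euclidean distance has the stated exact values", {
  set.seed(4)
  x <- matrix(rnorm(2 * 9), 2, 9)
  expect_equal(weighted_euclidean(x, x), 0)
  # a single center-frame difference of delta in one feature
  y <- x
  delta <- 0.7
  y[1, 5] <- y[1, 5] + delta
  w <- build_weights(9, 9)$weights
  expect_equal(weighted_euclidean(x, y), sqrt(w[5]) * delta)
  expect_equal(weighted_euclidean(x, y), weighted_euclidean(y, x))
  expect_error(weighted_euclidean(x, matrix(0, 3, 9)), "mismatch")
  # unequal lengths: strictly positive and defined
  z <- x[, 1:5]
  expect_gt(weighted_euclidean(x, z), 0)
})

test_that("linear warp shifts, stretches and reduces to identity", {
  set.seed(5)
  x <- matrix(rnorm(3 * 40), 3, 40)
  expect_equal(warp_sequence(x, c(0, 1), 40, 40), x, tolerance = 1e-12)
  # a delta spike moves by tau * len frames
  spike <- matrix(0, 1, 100)
  spike[1, 51] <- 1
  for (k in c(-8, 5)) {
    warped <- warp_sequence(spike, c(k / 100, 1), 100, 100)
    expect_equal(which.max(warped[1, ]), 51 - k, tolerance = 1)
  }
  # s = 2 doubles the slope of a ramp over the sampled window
  ramp <- matrix(seq(0, 1, length.out = 100), 1, 100)
  w2 <- warp_sequence(ramp, c(0, 2), 100, 100)
  slopes <- diff(w2[1, 1:40])
  expect_equal(slopes, rep(2 * diff(ramp[1, 1:2]), 39), tolerance = 1e-9)
})

test_that("warp penalty matches its closed form", {
  expect_equal(warp_penalty(0, 1), 0)
  expect_equal(warp_penalty(1, 1), pi / 4)
  expect_equal(warp_penalty(0, 2), 1.5 * pi / 4)
  expect_true(all(warp_penalty(runif(10, -1, 1), runif(10, 0.5, 2)) >= 0))
})

test_that("alignment loss decomposes into distance plus weighted penalty", {
  tmpl <- random_template(60, 2, seed = 10)
  q <- random_template(60, 2, seed = 11)
  p <- c(0.03, 1.05)
  manual <- weighted_euclidean(warp_sequence(q, p, 60, 60), tmpl)
  expect_equal(alignment_loss(q, tmpl, p, alpha = 0), manual)
  expect_equal(alignment_loss(q, tmpl, p, alpha = 2),
               manual + 2 * warp_penalty(p[1], p[2]))
  expect_equal(alignment_loss(tmpl, tmpl, c(0, 1), alpha = 5), 0)
  a <- seq(0, 3, by = 0.5)
  losses <- vapply(a, function(al) alignment_loss(q, tmpl, p, al), numeric(1))
  expect_true(all(diff(losses) > 0))  # strictly increasing when penalty > 0
})

test_that("alignment recovers known warps and never loses to identity", {
  set.seed(21)
  errs <- matrix(NA_real_, 20, 2)
  for (i in 1:20) {
    tmpl <- random_template(sample(60:90, 1), 3)
    tau <- runif(1, -0.1, 0.1)
    s <- runif(1, 0.8, 1.2)
    # query built so that warping it by (tau, s) reproduces the template
    q <- warp_sequence(tmpl, c(-tau / s, 1 / s),
                       round(ncol(tmpl) * s), ncol(tmpl))
    p <- linear_align(q, tmpl, alpha = 0)
    errs[i, ] <- c(abs(p$tau_w - tau), abs(p$s_w - s))
    expect_lte(p$cost,
               alignment_loss(q, tmpl, c(0, 1), alpha = 0) + 1e-9)
  }
  expect_lte(median(errs[, 1]), 0.01)
  expect_lte(median(errs[, 2]), 0.02)
})

test_that("aligning a sequence to itself returns the identity transform", {
  tmpl <- random_template(70, 3, seed = 33)
  p <- linear_align(tmpl, tmpl, alpha = 0.5)
  expect_lt(abs(p$tau_w), 1e-3)
  expect_lt(abs(p$s_w - 1), 1e-3)
  expect_lt(p$cost, 1e-4)
  expect_equal(p$cost, alignment_loss(tmpl, tmpl, p, alpha = 0.5))
})

test_that("a dominant penalty pushes the solution to the identity", {
  tmpl <- random_template(50, 2, seed = 40)
  q <- random_template(55, 2, seed = 41)
  # raw scale: the normalized-domain identity (0, 1)
  p <- linear_align(q, tmpl, alpha = 1e6, penalty_scale = "raw")
  expect_lt(abs(p$tau_w), 1e-3)
  expect_lt(abs(p$s_w - 1), 1e-3)
  # effective scale: zero real dilation, s = len_t / len_q
  pe <- linear_align(q, tmpl, alpha = 1e6, penalty_scale = "effective")
  expect_lt(abs(pe$tau_w), 1e-3)
  expect_lt(abs(pe$s_w - 50 / 55), 1e-3)
})

test_that("sampled optimization agrees with the dense grid oracle", {
  set.seed(55)
  for (i in 1:8) {
    tmpl <- random_template(sample(40:70, 1), 2)
    q <- warp_sequence(tmpl, c(runif(1, -0.08, 0.08), runif(1, 0.85, 1.18)),
                       sample(40:70, 1), ncol(tmpl))
    alpha <- runif(1, 0, 0.5)
    p <- linear_align(q, tmpl, alpha = alpha)
    g <- grid_align(q, tmpl, alpha = alpha)
    expect_lte(abs(p$tau_w - g$tau_w), 0.002)
    expect_lte(abs(p$s_w - g$s_w), 0.002)
    expect_lte(p$cost, g$cost + 1e-4)
  }
})

test_that("stored cost always equals the loss at the stored parameters", {
  set.seed(60)
  for (i in 1:5) {
    tmpl <- random_template(50, 2)
    q <- random_template(sample(40:60, 1), 2)
    alpha <- runif(1, 0, 2)
    p <- linear_align(q, tmpl, alpha = alpha)
    expect_equal(p$cost, alignment_loss(q, tmpl, p, alpha = alpha),
                 tolerance = 1e-12)
  }
})
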