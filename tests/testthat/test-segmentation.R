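test_that("difference images are normalized with degenerate guard", {
  f <- matrix(100L, 8, 8)
  g <- f; g[3, 5] <- 500L
  st <- zstack(list(f, f, g, f, f), spacing_um = 10)

  d_same <- difference_image(st, 1, 2)
  expect_true(all(d_same$values == 0))

  d_one <- difference_image(st, 1, 3)
  expect_equal(d_one$values[3, 5], 1)
  expect_equal(sum(d_one$values), 1)

  expect_error(difference_image(st, 1, 9), "out of bounds")
  expect_error(difference_image(st, 2, 2), "must differ")
})

test_that("component labelling is 8-connected and deterministic", {
  b <- matrix(0L, 6, 6)
  b[cbind(1:4, 1:4)] <- 1L          # diagonal chain: one object under 8-conn
  b[6, 6] <- 1L
  lab <- label_components(b)
  expect_identical(max(lab), 2L)
  expect_identical(length(unique(lab[cbind(1:4, 1:4)])), 1L)
  expect_identical(label_components(matrix(0L, 4, 4)), matrix(0L, 4, 4))
})

test_that("initial mask applies Otsu, labelling and the size filter", {
  v <- matrix(0, 80, 80)
  v[10:30, 10:30] <- 0.9       # 441 px
  v[50:70, 40:60] <- 0.85      # 441 px
  v[5, 70:74] <- 0.95          # 5 px artifact
  m <- initial_mask(v, seg_params(min_object_px = 50))
  expect_identical(max(m), 2L)
  expect_identical(sort(unique(as.vector(m))), c(0L, 1L, 2L))

  expect_identical(max(initial_mask(matrix(0, 10, 10))), 0L)
})

test_that("raising the size filter never increases the object count", {
  set.seed(14)
  v <- matrix(0, 64, 64)
  for (i in 1:6) {
    r <- sample(5:55, 1); c <- sample(5:55, 1); w <- sample(2:8, 1)
    v[r:(r + w), c:(c + w)] <- runif(1, 0.7, 1)
  }
  counts <- vapply(c(1, 5, 20, 60, 120), function(px)
    max(initial_mask(v, seg_params(min_object_px = px))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("contours at the guide's support are a fixed point", {
  g <- matrix(0.05, 60, 60)
  g[10:25, 10:25] <- 0.9
  g[35:50, 30:45] <- 0.85
  init <- initial_mask(g, seg_params(min_object_px = 10))
  expect_identical(max(init), 2L)
  out <- evolve_contours(init, g, seg_params(expansion_bias = 0,
                                             min_object_px = 10))
  for (k in 1:2)
    expect_gte(jaccard(out == k, init == k), 0.95)
})

test_that("evolution preserves labels and never merges regions", {
  g <- matrix(0.1, 40, 40)
  g[5:18, 5:18] <- 0.9
  g[5:18, 20:33] <- 0.9        # two touching-support blobs, 1 px apart
  init <- matrix(0L, 40, 40)
  init[10:12, 10:12] <- 1L
  init[10:12, 25:27] <- 2L
  out <- evolve_contours(init, g, seg_params(max_iterations = 100))
  expect_identical(sort(unique(as.vector(out))), c(0L, 1L, 2L))
  # grown, but never 8-adjacent across labels
  expect_gt(sum(out == 1L), sum(init == 1L))
  r1 <- which(out == 1L, arr.ind = TRUE)
  r2 <- which(out == 2L, arr.ind = TRUE)
  mindist <- min(outer(r1[, 2], r2[, 2], function(a, b) abs(a - b)))
  expect_gte(mindist, 1)

  empty <- matrix(0L, 40, 40)
  expect_identical(evolve_contours(empty, g), empty)
})

test_that("segment_stack recovers planted cells and is deterministic", {
  sim <- generate_zstack(small_spec(seed = 12))
  st <- sim$stack
  q <- suppressWarnings(select_frames_maxinfo(st))
  p <- seg_params(min_object_px = 20)
  m1 <- segment_stack(st, q, p)
  m2 <- segment_stack(st, q, p)
  expect_identical(m1, m2)
  counts <- match_detections(m1, sim$truth$centers)
  expect_gte(counts$recall, 2 / 3)
})

test_that("a cell-free noiseless stack segments to zero objects", {
  sim <- generate_zstack(small_spec(seed = 1, n_cells = 0L, noise_sigma = 0))
  st <- sim$stack
  strong <- difference_image(st, 1, n_frames(st))
  expect_identical(max(initial_mask(strong)), 0L)
})
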