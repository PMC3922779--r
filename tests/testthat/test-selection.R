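test_that("linearization concatenates columns top to bottom", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)      # [[1,0],[0,1]] by rows
  expect_identical(linearize(m), "1001")
  expect_identical(linearize(matrix(1L, 3, 3)), "111111111")
  # column order on a non-square grid
  m2 <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 2, 3)
  expect_identical(linearize(m2), "110010")
  # transposing swaps to row-major traversal
  expect_identical(linearize(t(m2)),
                   paste(apply(m2, 1, paste, collapse = ""), collapse = ""))
})

test_that("Otsu binarization separates a two-level image exactly", {
  set.seed(3)
  m <- matrix(sample(c(10L, 200L), 400, TRUE), 20, 20)
  b <- binarize_otsu(m)
  expect_identical(b == 1L, m == 200L)
  expect_error(binarize_otsu(matrix(5L, 4, 4)), "degenerate histogram")
})

test_that("Otsu misclassification on a two-Gaussian mixture is below 1%", {
  set.seed(4)
  lab <- matrix(sample(c(0L, 1L), 128 * 128, TRUE), 128, 128)
  m <- matrix(round(rnorm(128 * 128, mean = ifelse(lab == 1, 180, 50),
                          sd = 10)), 128, 128)
  m[m < 0] <- 0L
  b <- binarize_otsu(m)
  expect_lt(mean(b != lab), 0.01)
})

test_that("in-focus detection minimizes entropy with low-index tie-break", {
  st <- two_level_stack(n = 21, focus = 12)
  expect_identical(as.integer(find_in_focus(st)), 12L)
  expect_length(attr(find_in_focus(st), "profile"), 21L)

  set.seed(6)
  f <- matrix(sample.int(4096, 64 * 64, TRUE) - 1L, 64, 64)
  ties <- zstack(rep(list(f), 6), spacing_um = 10)
  expect_identical(as.integer(find_in_focus(ties)), 1L)
})

test_that("a five-frame stack admits exactly one quad", {
  sim <- generate_zstack(small_spec(seed = 2, n_frames = 5L))
  q <- suppressWarnings(select_frames_maxinfo(sim$stack))
  expect_identical(quad_indices(q), c(1L, 2L, 4L, 5L))
  expect_identical(q$i0, 3L)
})

test_that("maxinfo equals an independently coded brute-force enumeration", {
  for (seed in c(3, 8, 21)) {
    sim <- generate_zstack(small_spec(seed = seed, cell_z_jitter_um = 5))
    st <- sim$stack
    enc <- frame_encodings(st)
    D <- ncd_matrix(enc)
    q <- suppressWarnings(select_frames_maxinfo(st, encodings = enc, D = D))
    cs <- vapply(enc, function(e) e$c_size, numeric(1))
    oracle <- brute_force_quad(cs, unclass(D), q$i0, n_frames(st))
    expect_identical(quad_indices(q), as.integer(oracle$indices))
    expect_equal(q$psi, oracle$psi, tolerance = 1e-12)
  }
})

test_that("maxinfo psi dominates the fixed strategy's psi", {
  for (seed in 1:4) {
    sim <- generate_zstack(small_spec(seed = seed))
    st <- sim$stack
    enc <- frame_encodings(st)
    D <- ncd_matrix(enc)
    q <- suppressWarnings(select_frames_maxinfo(st, encodings = enc, D = D))
    qf <- suppressWarnings(
      select_frames_fixed(st, encodings = enc, D = D))
    expect_gte(q$psi, qf$psi)
  }
})

test_that("fixed offsets convert to frame counts by round-half-away", {
  # 3 um spacing: 10 um -> 3 frames, 25 um -> 8 frames around frame 12
  st3 <- two_level_stack(n = 21, focus = 12, spacing_um = 3)
  q <- select_frames_fixed(st3)
  expect_identical(quad_indices(q), c(4L, 9L, 15L, 20L))

  # 10 um spacing: the 25 um strong offset rounds up to 3 frames (30 um)
  st10 <- two_level_stack(n = 21, focus = 12, spacing_um = 10)
  q10 <- select_frames_fixed(st10)
  expect_identical(quad_indices(q10), c(9L, 11L, 13L, 15L))
  expect_identical(q10$i0, 12L)

  # focus too near the boundary for +-30 um
  st_edge <- two_level_stack(n = 7, focus = 3, spacing_um = 10)
  expect_error(suppressWarnings(select_frames_fixed(st_edge)),
               "exceed stack extent")
})

test_that("frame selection is deterministic", {
  sim <- generate_zstack(small_spec(seed = 5))
  q1 <- suppressWarnings(select_frames_maxinfo(sim$stack))
  q2 <- suppressWarnings(select_frames_maxinfo(sim$stack))
  expect_identical(quad_indices(q1), quad_indices(q2))
  expect_identical(q1$psi, q2$psi)
})

test_that("quad invariants hold: ordered indices straddling the focus", {
  sim <- generate_zstack(small_spec(seed = 9))
  q <- suppressWarnings(select_frames_maxinfo(sim$stack))
  idx <- quad_indices(q)
  expect_true(all(diff(c(idx[1:2], q$i0, idx[3:4])) > 0))
  expect_true(all(idx >= 1 & idx <= n_frames(sim$stack)))
})
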