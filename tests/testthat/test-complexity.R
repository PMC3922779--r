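test_that("histogram entropy matches closed forms", {
  const <- matrix(100L, 16, 16)
  expect_equal(shannon_entropy(const, bit_depth = 12), 0)

  # half the pixels at 0, half at the top of the range: two equiprobable bins
  two <- matrix(c(rep(0L, 128), rep(4095L, 128)), 16, 16)
  expect_equal(shannon_entropy(two, bit_depth = 12, bins = 256), 1)

  # four equally frequent, bin-separated intensities
  four <- matrix(rep(c(0L, 1024L, 2048L, 3072L), each = 64), 16, 16)
  expect_equal(shannon_entropy(four, bit_depth = 12, bins = 256), 2)
})

test_that("entropy depends only on the histogram, not pixel positions", {
  set.seed(1)
  m <- matrix(sample.int(4096, 400, replace = TRUE) - 1L, 20, 20)
  perm <- matrix(sample(as.vector(m)), 20, 20)
  expect_identical(shannon_entropy(m), shannon_entropy(perm))
})

test_that("pixel-integral entropy variant is available and sane", {
  const <- matrix(7L, 8, 8)
  expect_equal(shannon_entropy(const, method = "integral"), 0)
  set.seed(2)
  m <- matrix(sample.int(4096, 256, replace = TRUE) - 1L, 16, 16)
  expect_gt(shannon_entropy(m, method = "integral"), 0)
})

test_that("compression size behaves like a complexity proxy", {
  expect_error(compression_size(""), "non-empty")
  expect_gt(compression_size("1"), 0)

  zeros <- strrep("0", 10000)
  # pinned from a single oracle run of the compressor
  expect_identical(compression_size(zeros), 44L)

  rand <- maxinfo:::with_fixed_rng(7,
    paste(sample(c("0", "1"), 10000, TRUE), collapse = ""))
  expect_gt(compression_size(rand), compression_size(zeros))
})

test_that("compression cache memoizes by string identity", {
  cache <- new.env(parent = emptyenv())
  s <- strrep("01", 2000)
  reset_compression_calls()
  a <- compression_size(s, cache = cache)
  b <- compression_size(s, cache = cache)
  expect_identical(a, b)
  expect_identical(compression_calls(), 1L)
})

test_that("ncd reproduces the limiting similarity properties", {
  reg <- strrep("01", 5000)
  expect_lt(ncd(reg, reg), 0.15)          # identical regular strings ~ 0

  r1 <- maxinfo:::with_fixed_rng(7,
    paste(sample(c("0", "1"), 10000, TRUE), collapse = ""))
  r2 <- maxinfo:::with_fixed_rng(8,
    paste(sample(c("0", "1"), 10000, TRUE), collapse = ""))
  v <- ncd(r1, r2)                        # independent random strings ~ 1
  expect_gte(v, 0.85)
  expect_lte(v, 1.15)

  # a random string against itself: bzip2 does not exploit the distant
  # repeat, so the value is well above the idealized 0; pinned regression
  expect_equal(ncd(r1, r1), 0.3945498, tolerance = 1e-6)
})

test_that("ncd is exactly symmetric through canonical concatenation", {
  set.seed(5)
  for (i in 1:5) {
    a <- paste(sample(c("0", "1"), 500, TRUE), collapse = "")
    b <- paste(sample(c("0", "1"), 700, TRUE), collapse = "")
    expect_identical(ncd(a, b), ncd(b, a))
  }
})

mock_encoding <- function(index, s) {
  list(frame_index = as.integer(index), binary = NULL, string = s,
       c_size = compression_size(s))
}

test_that("ncd_matrix is symmetric with an exact-zero diagonal", {
  set.seed(9)
  enc <- lapply(1:4, function(i)
    mock_encoding(i, paste(sample(c("0", "1"), 400, TRUE), collapse = "")))
  D <- ncd_matrix(enc)
  expect_identical(dim(unclass(D)), c(4L, 4L))
  expect_identical(unname(diag(unclass(D))), rep(0, 4))
  expect_identical(unclass(D), t(unclass(D)))
  expect_identical(length(unique(D[upper.tri(D)])), 6L)

  twin <- list(mock_encoding(1, strrep("01", 500)),
               mock_encoding(2, strrep("01", 500)))
  expect_lt(ncd_matrix(twin)[1, 2], 0.15)
})

test_that("ncd_matrix performs one pair compression per unordered pair", {
  set.seed(11)
  enc <- lapply(1:21, function(i)
    mock_encoding(i, paste(sample(c("0", "1"), 200, TRUE), collapse = "")))
  reset_compression_calls()
  ncd_matrix(enc)
  expect_identical(compression_calls(), 210L)   # 21 choose 2
})

test_that("set complexity matches its closed forms and a brute-force oracle", {
  # equal sizes, all pairs half-similar: Psi = 0.25 * c
  D_half <- matrix(0.5, 4, 4); diag(D_half) <- 0
  expect_equal(set_complexity(rep(1000, 4), D_half), 250)

  # identical strings: x(1 - x) vanishes
  D_zero <- matrix(0, 4, 4)
  expect_equal(set_complexity(rep(1000, 4), D_zero), 0)

  # hand-chosen 3-string mock against an independent literal evaluation
  C <- c(100, 200, 300)
  D <- matrix(c(0, 0.3, 0.8,
                0.3, 0, 0.55,
                0.8, 0.55, 0), 3, 3, byrow = TRUE)
  acc <- 0
  for (i in 1:3) for (j in 1:3) if (i != j)
    acc <- acc + C[i] * D[i, j] * (1 - D[i, j])
  expect_equal(set_complexity(C, D), acc / 6, tolerance = 1e-12)

  expect_error(set_complexity(c(1, 2), D), "dimension mismatch")
})

test_that("set complexity is permutation invariant and bounded", {
  set.seed(13)
  C <- runif(5, 100, 1000)
  D <- matrix(runif(25, 0, 1), 5, 5)
  D <- (D + t(D)) / 2; diag(D) <- 0
  psi <- set_complexity(C, D)
  p <- sample(5)
  expect_equal(set_complexity(C[p], D[p, p]), psi, tolerance = 1e-12)
  # with all NCD <= 1 each factor is at most 0.25
  expect_lte(psi, 0.25 * max(C))
})
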