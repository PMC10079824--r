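test_that("average pooling compresses by the window with exact means", {
  expect_identical(poolAverage(c(1, 2, 3, 4, 5, 6, 7, 8), 8), 4.5)
  expect_length(poolAverage(rep(1, 512), 8), 64L)
  expect_identical(poolAverage(numeric(0), 8), numeric(0))
  expect_equal(poolAverage(rep(3.5, 100), 10), rep(3.5, 10))
  # trailing partial window averages its actual length
  expect_equal(poolAverage(c(1, 1, 4), 2), c(1, 4))
  M <- matrix(1:16, nrow = 2, byrow = TRUE)
  P <- poolProfiles(M, 4)
  expect_equal(P[1, ], c(mean(1:4), mean(5:8)))
  expect_equal(P[2, ], c(mean(9:12), mean(13:16)))
})

test_that("z-normalization uses population moments and guards degeneracy", {
  expect_equal(normalizeProfile(c(0, 2)), c(-1, 1))
  withr::with_seed(1, {
    x <- rnorm(100, 5, 3)
    z <- normalizeProfile(x)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(mean(z^2), 1, tolerance = 1e-12)
  })
  expect_identical(normalizeProfile(rep(4, 8)), rep(0, 8))
  # sample-level moments: profile equal to the sample mean maps to zeros
  expect_identical(normalizeProfile(rep(30, 8), center = 30, scale = 5),
                   rep(0, 8))
  expect_error(normalizeProfile(1:3, center = 1, scale = 0),
               class = "svw_validation")
})

test_that("SAX discretisation follows the equiprobable-cell convention", {
  expect_identical(saxTransform(c(-1, -0.1, 0.1, 1), 4), c(0L, 1L, 2L, 3L))
  # a value on a cell boundary takes the upper symbol
  expect_identical(saxTransform(rep(0, 5), 24), rep(12L, 5))
  expect_error(saxTransform(c(1, NaN), 4), class = "svw_validation")
  withr::with_seed(3, {
    x <- rnorm(500)
    s <- saxTransform(x, 24)
    expect_true(all(s >= 0 & s < 24))
    # monotone: pointwise ordered inputs give pointwise ordered symbols
    u <- sort(rnorm(50)); v <- u + abs(rnorm(50))
    expect_true(all(saxTransform(u, 24) <= saxTransform(v, 24)))
  })
})

test_that("MINDIST matches the closed form and lower-bounds Euclidean", {
  expect_identical(saxMindist(c(0L, 5L, 23L), c(0L, 5L, 23L), 3, 24), 0)
  expect_identical(saxMindist(c(3L, 7L), c(4L, 6L), 2, 24), 0)  # adjacent
  beta <- saxBreakpoints(4)
  expect_equal(saxMindist(c(0L, 3L), c(3L, 0L), 2, 4),
               sqrt(2) * (beta[3] - beta[1]))
  expect_equal(saxMindist(c(0L, 3L), c(3L, 0L), 2, 4), 1.9077, tolerance = 1e-4)
  expect_error(saxMindist(c(0L, 1L), c(0L, 1L, 2L), 3, 4),
               class = "svw_validation")
  withr::with_seed(5, {
    for (i in 1:50) {
      u <- normalizeProfile(rnorm(32)); v <- normalizeProfile(rnorm(32))
      d <- saxMindist(saxTransform(u, 24), saxTransform(v, 24), 32, 24)
      expect_lte(d, sqrt(sum((u - v)^2)) + 1e-12)
      # symmetry
      expect_identical(d, saxMindist(saxTransform(v, 24),
                                     saxTransform(u, 24), 32, 24))
    }
  })
})

test_that("sliding segmentation honours length, stride and degenerate input", {
  w <- saxTransform(normalizeProfile(sin(seq(0, 6, length.out = 64))), 24)
  segs <- segmentSliding(w, 32)
  expect_identical(nrow(segs), 33L)
  expect_identical(ncol(segs), 32L)
  expect_identical(attr(segs, "offsets"), 0:32)
  expect_identical(segs[5, ], w[5:36])

  one <- segmentSliding(w[1:32], 32)
  expect_identical(nrow(one), 1L)
  expect_identical(one[1, ], w[1:32])

  expect_message(none <- segmentSliding(w[1:10], 32))
  expect_identical(nrow(none), 0L)

  expect_identical(nrow(segmentSliding(w, 32, step = 4)), 9L)
})

test_that("DTW matches the exhaustive path-enumeration oracle", {
  # minimal cumulative squared cost on the 3 x 2 grid is 0: the path
  # (1,1),(2,1),(3,2) aligns every point at zero cost
  expect_identical(dtwDistance(c(0, 0, 1), c(0, 1)),
                   bruteDtw(c(0, 0, 1), c(0, 1)))
  expect_identical(bruteDtw(c(0, 0, 1), c(0, 1)), 0)
  withr::with_seed(9, {
    for (i in 1:40) {
      x <- round(rnorm(sample(2:6, 1)), 2)
      y <- round(rnorm(sample(2:6, 1)), 2)
      expect_equal(dtwDistance(x, y), bruteDtw(x, y), tolerance = 1e-12)
      expect_identical(dtwDistance(x, y), dtwDistance(y, x))
    }
    # never exceeds Euclidean distance for equal lengths
    for (i in 1:20) {
      x <- rnorm(20); y <- rnorm(20)
      expect_lte(dtwDistance(x, y), sqrt(sum((x - y)^2)) + 1e-12)
    }
  })
  expect_identical(dtwDistance(1:7, 1:7), 0)
  expect_error(dtwDistance(numeric(0), 1), class = "svw_validation")
})
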