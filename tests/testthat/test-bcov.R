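test_that("encoding writes two little-endian bytes per position and inverts", {
  f <- withr::local_tempfile(fileext = ".bcov")
  expect_identical(as.integer(encodeBcov(c(0L, 1L, 2L), f)), 6L)
  expect_identical(file.size(f), 6)
  expect_identical(decodeBcov(f), c(0L, 1L, 2L))

  # hand-decoded payload: 01 00 | 00 00 | ff ff -> 1, 0, 65535
  expect_identical(decodeBcov(as.raw(c(1, 0, 0, 0, 255, 255))),
                   c(1L, 0L, 65535L))

  # empty track
  f2 <- withr::local_tempfile(fileext = ".bcov")
  expect_identical(as.integer(encodeBcov(integer(0), f2)), 0L)
  expect_identical(decodeBcov(f2), integer(0))

  # clamping at the two-byte ceiling, rejection of negatives
  f3 <- withr::local_tempfile(fileext = ".bcov")
  encodeBcov(70000, f3)
  expect_identical(decodeBcov(f3), 65535L)
  expect_error(encodeBcov(-1L, f3), class = "svw_validation")
})

test_that("decode rejects odd payloads and round-trips clamp arbitrary tracks", {
  expect_error(decodeBcov(as.raw(c(1, 0, 0))), class = "svw_format")

  f <- withr::local_tempfile(fileext = ".bcov")
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(0:300, 1)
      d <- sample(c(0:70000), n, replace = TRUE)
      encodeBcov(d, f)
      expect_identical(decodeBcov(f), pmin(as.integer(d), 65535L))
      expect_identical(file.size(f), 2 * n)
    }
  })
})

test_that("multi-contig files slice identically to in-memory tracks", {
  withr::with_seed(7, {
    tracks <- list(CoverageTrack("chr1", sample(0:80, 3000, TRUE)),
                   CoverageTrack("chr2", sample(0:80, 1500, TRUE)))
    f <- withr::local_tempfile(fileext = ".bcov")
    idx <- writeBcov(tracks, f)
    expect_identical(idx$offset, c(0, 6000))
    expect_true(all(idx$offset %% 2 == 0))
    back <- readBcov(f)
    expect_identical(trackDepths(back$chr2), trackDepths(tracks[[2]]))
    for (i in 1:25) {
      ctg <- sample(c("chr1", "chr2"), 1)
      tr <- tracks[[match(ctg, c("chr1", "chr2"))]]
      hw <- sample(1:64, 1)
      ctr <- sample(seq(hw + 1, trackLength(tr) - hw), 1)
      expect_identical(sliceWindow(f, ctg, ctr, hw),
                       sliceWindow(tr, ctg, ctr, hw))
    }
    expect_error(readBcov(f, "chrX"), class = "svw_lookup")
  })
})

test_that("window slicing follows the centre convention and flags bounds", {
  tr <- CoverageTrack("chr1", c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90))
  # half-width w at centre p covers [p - w, p + w - 1]
  expect_identical(sliceWindow(tr, "chr1", 5, 2), c(20L, 30L, 40L, 50L))
  expect_length(sliceWindow(CoverageTrack("chr1", rep(1L, 10000)),
                            "chr1", 5000, 256), 512L)
  expect_error(sliceWindow(CoverageTrack("chr1", rep(1L, 10000)),
                           "chr1", 1, 256), class = "svw_out_of_bounds")
  expect_identical(sliceWindow(tr, "chr1", 9, 2), c(60L, 70L, 80L, 90L))
  expect_error(sliceWindow(tr, "chr1", 10, 2), class = "svw_out_of_bounds")
  expect_error(sliceWindow(tr, "chr2", 5, 2), class = "svw_lookup")
})

test_that("bedGraph densification expands intervals with explicit zeros", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t3\t7", f)
  expect_identical(trackDepths(bedgraphToTracks(f, c(chr1 = 5L))$chr1),
                   c(7L, 7L, 7L, 0L, 0L))

  writeLines(character(0), f)
  expect_identical(trackDepths(bedgraphToTracks(f, c(chr1 = 4L))$chr1),
                   rep(0L, 4))

  writeLines(c("chr1\t0\t2\t1", "chr1\t2\t4\t2"), f)
  expect_identical(trackDepths(bedgraphToTracks(f, c(chr1 = 4L))$chr1),
                   c(1L, 1L, 2L, 2L))

  writeLines(c("chr1\t0\t3\t1", "chr1\t2\t4\t2"), f)
  expect_error(bedgraphToTracks(f, c(chr1 = 4L)), class = "svw_format")
  writeLines("chr1\t0\t9\t1", f)
  expect_error(bedgraphToTracks(f, c(chr1 = 4L)), class = "svw_format")
})

test_that("bedGraph export round-trips through densification", {
  withr::with_seed(11, {
    tr <- CoverageTrack("chr1", sample(0:5, 400, TRUE))
    f <- withr::local_tempfile(fileext = ".bedGraph")
    trackToBedgraph(tr, f)
    back <- bedgraphToTracks(f, c(chr1 = 400L))$chr1
    expect_identical(trackDepths(back), trackDepths(tr))
  })
})

test_that("CoverageTrack validity enforces the depth domain", {
  expect_error(CoverageTrack("chr1", c(1, -2)))
  expect_error(CoverageTrack("chr1", 70000))
  expect_error(CoverageTrack("chr1", 1.5))
  expect_s4_class(CoverageTrack("chr1", integer(0)), "CoverageTrack")
})
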