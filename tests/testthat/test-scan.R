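test_that("a profile synthesised from a motif scores zero at its offset", {
  cfg <- SVWaveConfig()
  tpl <- motifTemplates()$DEL_DIP
  prof <- plantedMotifDataset(tpl, nProfiles = 1, noiseSd = 0, seed = 1)[1, ]
  word <- saxTransform(normalizeProfile(poolAverage(prof, 8)), 24)
  motif <- word[17:48]   # the template occupies pooled bins 17..48
  sc <- scanProfile(prof, motif, cfg)
  expect_identical(sc$score[1], 0)
  expect_identical(sc$offset[1], 16L)
  # uniform scaling of the raw profile does not change the scores
  sc3 <- scanProfile(3 * prof, motif, cfg)
  expect_equal(sc3$score, sc$score)
  expect_identical(sc3$offset, sc$offset)
})

test_that("profile scanning equals brute-force sliding MINDIST", {
  cfg <- SVWaveConfig()
  withr::with_seed(23, {
    prof <- rpois(512, 30)
    motif <- sample(0:23, 32, TRUE)
    sc <- scanProfile(prof, motif, cfg)
    word <- saxTransform(normalizeProfile(poolAverage(prof, 8)), 24)
    brute <- vapply(0:32, function(o)
      saxMindist(word[(o + 1):(o + 32)], motif, 256, 24), numeric(1))
    got <- sc$score[order(sc$offset)]
    expect_equal(got, brute, tolerance = 1e-12)
  })
  # flat profile vs a step-shaped motif finds nothing at a strict threshold
  flat <- rep(30, 512)
  step <- c(rep(20L, 16), rep(2L, 16))
  expect_identical(nrow(scanProfile(flat, step, cfg, threshold = 1)), 0L)
  # too-short profile yields an empty result with a message
  expect_message(none <- scanProfile(rep(30, 100), step, cfg))
  expect_identical(nrow(none), 0L)
})

test_that("track scanning tiles, merges overlaps and respects the stride", {
  cfg <- SVWaveConfig(seed = 2)
  tpl <- motifTemplates()$DEL_DIP
  prof <- plantedMotifDataset(tpl, nProfiles = 1, noiseSd = 0, seed = 1)[1, ]
  word <- saxTransform(normalizeProfile(poolAverage(prof, 8)), 24)
  motifs <- data.frame(motifId = "dip", sax = saxToString(word[17:48], 24),
                       anchor = 16L)
  withr::with_seed(3, {
    depths <- rpois(6000, 30)
    depths[2501:2756] <- rep(pmax(0, round(tpl)), each = 8)
  })
  tr <- CoverageTrack("chr1", depths)
  hits <- scanTrack(tr, motifs, cfg, threshold = 6)
  expect_gt(nrow(hits), 0L)
  best <- hits[which.min(hits$score), ]
  # matched span covers the planted template
  expect_lt(abs(best$start - 2500), 9)
  # overlapping hits collapsed: no two retained dip hits overlap
  if (nrow(hits) > 1L) {
    o <- order(hits$start)
    expect_true(all(hits$start[o][-1] >= hits$end[o][-nrow(hits)]))
  }
  # a flat track has no hits at a strict threshold
  withr::with_seed(4, flat <- CoverageTrack("chr1", rpois(4000, 30)))
  expect_identical(nrow(scanTrack(flat, motifs, cfg, threshold = 1)), 0L)
  # doubling the stride never creates hits absent at stride 8
  h8 <- scanTrack(tr, motifs, cfg, stride = 8, threshold = 6)
  h16 <- scanTrack(tr, motifs, cfg, stride = 16, threshold = 6)
  expect_true(all(h16$score >= min(h8$score)))
  expect_true(all(paste(h16$start, h16$offset) %in%
                    paste(h8$start, h8$offset) |
                    h16$score >= min(h8$score)))
})

test_that("scan workflow validates motif compatibility", {
  tr <- CoverageTrack("chr1", rep(30L, 2000))
  cfg <- SVWaveConfig()
  expect_error(runScan(tr, NULL, cfg), class = "svw_validation")
  bad <- data.frame(motifId = "m", sax = saxToString(rep(1L, 16), 24))
  err <- tryCatch(runScan(tr, bad, cfg), error = function(e) e)
  expect_s3_class(err, "svw_config_mismatch")
  expect_match(conditionMessage(err), "segLen")
})

test_that("null-score calibration yields a usable threshold", {
  cfg <- SVWaveConfig()
  motif <- c(rep(20L, 16), rep(2L, 16))
  thr <- calibrateScanThreshold(motif, cfg, seed = 5, nNull = 30)
  expect_gt(thr, 0)
  # the calibrated threshold admits about 1% of null windows by design
  withr::with_seed(6, {
    sc <- scanProfile(rpois(512, 30), motif, cfg)
    expect_lt(mean(sc$score <= thr), 0.2)
  })
})
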