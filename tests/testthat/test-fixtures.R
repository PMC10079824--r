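test_that("simulated coverage matches analytic expectations per event class", {
  ev <- data.frame(svtype = c("DEL", "DEL", "DUP"),
                   start = c(2000L, 6000L, 10000L),
                   length = c(2000L, 2000L, 2000L),
                   genotype = c("HOM_ALT", "HET", "HOM_ALT"))
  sim <- simulateSample(simSpec(20000L, ev), seed = 4)
  d <- as.numeric(trackDepths(sim$track))
  inside <- function(i) d[ev$start[i]:(ev$start[i] + ev$length[i] - 1L)]
  se <- function(mu, n) 3 * sqrt(mu / n)
  expect_lt(mean(inside(1)), 1)                       # hom DEL: rate ~ 0
  expect_lt(abs(mean(inside(2)) - 15), se(15, 2000))  # het DEL: x0.5
  expect_lt(abs(mean(inside(3)) - 60), se(60, 2000))  # hom DUP: x2
  outside <- d[12500:20000]
  expect_lt(abs(mean(outside) - 30), se(30, 7500))    # baseline 30x

  flat <- simulateSample(simSpec(20000L), seed = 5)
  expect_lt(abs(mean(trackDepths(flat$track)) - 30), se(30, 20000))

  # emitted records all pass the default filters
  cfg <- SVWaveConfig()
  expect_identical(nrow(filterVariants(sim$variants, cfg)), nrow(ev))
})

test_that("inversion and insertion events dip locally at their breakpoints", {
  ev <- data.frame(svtype = c("INV", "INS"), start = c(3000L, 9000L),
                   length = c(2000L, 1L), genotype = "HOM_ALT")
  spec <- simSpec(12000L, ev)
  sim <- simulateSample(spec, seed = 6)
  d <- as.numeric(trackDepths(sim$track))
  expect_lt(mean(d[3000:3015]), 0.6 * 30)   # INV left-edge ramp
  expect_lt(mean(d[8990:9010]), 0.7 * 30)   # INS dip
  expect_gt(mean(d[3900:4100]), 25)         # INV interior keeps x1
  expect_identical(sim$variants$end[2], 9000L)  # INS has end == start

  overlapping <- data.frame(svtype = c("DEL", "DEL"),
                            start = c(1000L, 1500L), length = c(1000L, 200L),
                            genotype = "HOM_ALT")
  expect_error(simSpec(12000L, overlapping), class = "svw_validation")
})

test_that("negative-binomial noise is overdispersed relative to Poisson", {
  p <- simulateSample(simSpec(30000L), seed = 7)
  nb <- simulateSample(simSpec(30000L, noise = "nbinom", dispersion = 5),
                       seed = 7)
  expect_gt(var(as.numeric(trackDepths(nb$track))),
            1.5 * var(as.numeric(trackDepths(p$track))))
})

test_that("planted template pools embed the template exactly at the centre", {
  tpl <- motifTemplates()$DEL_DIP
  X0 <- plantedMotifDataset(tpl, nProfiles = 3, noiseSd = 0, seed = 1)
  # zero noise, zero jitter: all profiles identical
  expect_identical(X0[1, ], X0[2, ])
  # pooling recovers the template over the central 32 bins
  pooled <- poolAverage(X0[1, ], 8)
  expect_equal(pooled[17:48], tpl, tolerance = 1e-12)
  # SAX of the embedded template never inverts the template's ordering
  w <- saxTransform(normalizeProfile(pooled), 24)[17:48]
  wt <- saxTransform(normalizeProfile(tpl), 24)
  ord <- order(tpl)
  expect_false(is.unsorted(w[ord]))
  expect_false(is.unsorted(wt[ord]))

  withr::with_seed(2, {
    Xj <- plantedMotifDataset(tpl, nProfiles = 5, noiseSd = 2, seed = 3,
                              shiftJitter = 16L, stretchJitter = 0.1)
    expect_identical(dim(Xj), c(5L, 512L))
    expect_true(all(Xj >= 0))
  })
})

test_that("cohort fixtures round-trip through the extraction layer", {
  d <- withr::local_tempdir()
  fx <- writeCohortFixture(d, nSamples = 3, seed = 11)
  expect_true(file.exists(fx$vcf))
  v <- readSvVcf(fx$vcf)
  expect_identical(nrow(v$variants), nrow(fx$variants))
  expect_identical(unname(v$gt), unname(fx$gt))
  cfg <- SVWaveConfig()
  fl <- filterVariants(v$variants, cfg)
  expect_identical(nrow(fl), nrow(v$variants))  # all PASS and >= 20 bp
  loci <- deriveLoci(fl, cfg)
  prof <- extractProfiles(loci, as.list(fx$bcov), v$gt, cfg, ft = v$ft)
  expect_gt(ncol(prof), 0L)
  expect_identical(nrow(prof), 512L)
  info <- as.data.frame(profileInfo(prof))
  # the taxonomy present in the fixture reaches the profile set
  expect_true(all(c("L", "R", "spSV", "BP") %in% info$side) ||
                all(c("L", "R") %in% info$side))
  meta <- read.table(fx$meta, header = TRUE, sep = "\t")
  expect_identical(meta$sample_id, names(fx$bcov))
})
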