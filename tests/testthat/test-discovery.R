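test_that("reference nodes are monotone, mirrored and deterministic", {
  refs <- makeReferences(32, 24)
  expect_false(is.unsorted(refs$sin))
  expect_false(is.unsorted(rev(refs$cos)))
  # sin(t) = cos(pi/2 - t): under symmetric sampling the words mirror
  expect_identical(refs$sin, rev(refs$cos))
  expect_identical(makeReferences(32, 24), refs)
  expect_true(all(refs$sin >= 0 & refs$sin < 24))
})

test_that("similarity grouping handles degenerate neighbourhoods", {
  refs <- makeReferences(16, 8)
  same <- matrix(rep(c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L), each = 2), 20, 16,
                 byrow = TRUE)
  g <- knnSearchModified(same, refs, eps = 0.5, originalLength = 128,
                         alphabetSize = 8)
  expect_length(g, 1L)
  expect_identical(g[[1]]$size, 20L)
  expect_identical(g[[1]]$representative, same[1, ])

  far <- rbind(rep(0L, 16), rep(3L, 16), rep(7L, 16))
  g0 <- knnSearchModified(far, refs, eps = 0, originalLength = 128,
                          alphabetSize = 8)
  expect_length(g0, 3L)
  expect_true(all(vapply(g0, `[[`, integer(1), "size") == 1L))
  expect_error(knnSearchModified(far, refs, eps = -1, originalLength = 128,
                                 alphabetSize = 8), class = "svw_validation")
  expect_error(knnSearchModified(far[, 1:8], refs, eps = 1,
                                 originalLength = 64, alphabetSize = 8),
               class = "svw_validation")
})

test_that("the pruned search never evaluates more than all pairs and prunes
           dispersed data", {
  withr::with_seed(31, {
    refs <- makeReferences(32, 24)
    # dispersed: tight families at well-separated mean levels
    levels <- c(2L, 8L, 14L, 20L)
    words <- do.call(rbind, lapply(levels, function(lv)
      t(vapply(1:40, function(i)
        pmin(pmax(lv + sample(-1:1, 32, TRUE), 0L), 23L), integer(32)))))
    D <- bruteSaxDistMatrix(words, 256, 24)
    eps <- unname(quantile(D[upper.tri(D)], 0.05))
    g <- knnSearchModified(words, refs, eps, 256, 24)
    n <- nrow(words)
    expect_lte(attr(g, "n_eval"), n * (n - 1) / 2)
    expect_lt(attr(g, "n_eval"), n * (n - 1) / 2)  # strictly prunes here
    # and the pruning is lossless
    expect_identical(partitionOf(g), bruteGroups(words, eps, 256, 24))
  })
})

test_that("cluster scope selection applies the strictly-greater share rule", {
  mk <- function(s, n = 100L) c(rep(1L, s), rep(2L, n - s))
  expect_identical(selectClusterScope(mk(70)), 1L)
  expect_identical(sort(selectClusterScope(mk(50))), c(1L, 2L))
  # exactly at the threshold share both clusters are searched
  expect_identical(sort(selectClusterScope(mk(66))), c(1L, 2L))
  expect_identical(selectClusterScope(mk(67)), 1L)
  # the boundary share is the largest one that still searches both
  both <- vapply(60:75, function(s) length(selectClusterScope(mk(s))) == 2L,
                 logical(1))
  expect_identical(max((60:75)[both]), 66L)
  # larger cluster listed first when both are returned
  expect_identical(selectClusterScope(mk(40)), c(2L, 1L))
})

test_that("motif merging averages within families and respects the threshold", {
  a24 <- 24L
  w1 <- saxToString(rep(10L, 32), a24)
  out <- mergeMotifs(c(w1, w1, w1), mergeEps = 1, originalLength = 256,
                     alphabetSize = a24)
  expect_identical(out$sax, w1)
  expect_identical(out$support, 3)

  # two words differing by one adjacent symbol are MINDIST-0, so they merge;
  # the differing position averages (10 + 11)/2 = 10.5 -> round-half-even 10
  w2sym <- rep(10L, 32); w2sym[5] <- 11L
  out2 <- mergeMotifs(c(w1, saxToString(w2sym, a24)), mergeEps = 0,
                      originalLength = 256, alphabetSize = a24)
  expect_identical(out2$support, 2)
  expect_identical(stringToSax(out2$sax, a24)[5], 10L)

  # unequal supports weight the average: (1*10 + 3*11)/4 -> round 11
  out3 <- mergeMotifs(c(w1, saxToString(w2sym, a24)), mergeEps = 0,
                      originalLength = 256, alphabetSize = a24,
                      support = c(1, 3))
  expect_identical(stringToSax(out3$sax, a24)[5], 11L)

  far <- c(saxToString(rep(2L, 32), a24), saxToString(rep(20L, 32), a24),
           saxToString(rep(20L, 32), a24))
  out4 <- mergeMotifs(far, mergeEps = 0, originalLength = 256,
                      alphabetSize = a24, support = c(5, 2, 2))
  expect_identical(out4$support, 5)       # no merging at eps 0 across far words
  expect_identical(out4$sax, far[1])
  expect_error(mergeMotifs(character(0), 1, 256, a24),
               class = "svw_validation")
})

test_that("bootstrap discovery is deterministic and collapses a noiseless
           pool to one word", {
  tpl <- motifTemplates()$DEL_DIP
  X <- plantedMotifDataset(tpl, nProfiles = 30, noiseSd = 0, seed = 1)
  cfg <- testConfig(nBootstrap = 4, bootstrapSize = 16, seed = 1)
  cand <- bootstrapDiscover(X, cfg, seed = 2)
  # every profile identical: every subset's top representative is the same
  expect_identical(length(unique(cand$sax)), 1L)
  expect_identical(cand, bootstrapDiscover(X, cfg, seed = 2))
  expect_error(bootstrapDiscover(X[0, , drop = FALSE], cfg, seed = 1),
               class = "svw_validation")

  m1 <- discoverMotifs(plantedMotifDataset(tpl, 60, seed = 5), cfg, seed = 9)
  m2 <- discoverMotifs(plantedMotifDataset(tpl, 60, seed = 5), cfg, seed = 9)
  expect_identical(m1, m2)
})

test_that("SAX words serialise losslessly", {
  withr::with_seed(17, {
    for (a in c(4L, 24L, 30L)) {
      s <- sample(0:(a - 1L), 32, TRUE)
      expect_identical(stringToSax(saxToString(s, a), a), s)
    }
  })
  expect_error(stringToSax("zz", 24))
})
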