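# Independent oracles and shared fixtures for the test suite.

# Scaled-down discovery/clustering controls used throughout the tests; the
# statistical machinery is identical to the defaults, only the simulation
# sizes are smaller (the vignette documents the sizes used).
testConfig <- function(...) {
  args <- utils::modifyList(list(kmRestarts = 3, kmMaxIter = 8, dbaIter = 3),
                            list(...))
  do.call(SVWaveConfig, args)
}

# Exhaustive DTW oracle: enumerates every monotone warping path on the
# n x m grid by recursion and returns the square root of the minimal
# cumulative squared cost. Only usable for tiny inputs.
bruteDtw <- function(x, y) {
  n <- length(x); m <- length(y)
  rec <- function(i, j) {
    c0 <- (x[i] - y[j])^2
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  sqrt(rec(n, m))
}

# All-pairs SAX distance matrix via per-position cell accumulation.
bruteSaxDistMatrix <- function(words, originalLength, alphabetSize) {
  tab <- saxCellTable(alphabetSize)
  L <- ncol(words)
  D2 <- matrix(0, nrow(words), nrow(words))
  for (p in seq_len(L)) {
    cp <- tab[words[, p] + 1L, words[, p] + 1L]
    D2 <- D2 + cp^2
  }
  sqrt(originalLength / L) * sqrt(D2)
}

# Brute-force similarity grouping: single-linkage components of the
# all-pairs <=eps graph, via igraph.
bruteGroups <- function(words, eps, originalLength, alphabetSize) {
  D <- bruteSaxDistMatrix(words, originalLength, alphabetSize)
  g <- igraph::graph_from_adjacency_matrix(D <= eps, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  unname(lapply(split(seq_len(nrow(words)), comp), sort))
}

# Canonical partition representation of a similarity-group result.
partitionOf <- function(groups) {
  p <- lapply(groups, function(g) sort(g$members))
  p[order(vapply(p, min, integer(1)))]
}

# Textbook silhouette: s(i) = (b_i - a_i) / max(a_i, b_i) with a_i the mean
# within-cluster distance and b_i the smallest mean distance to another
# cluster.
bruteSilhouette <- function(D, labels) {
  n <- length(labels)
  mean(vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(D[i, labels == k]), numeric(1)))
    if (sum(own) == 1L) return(0)
    (b - a) / max(a, b)
  }, numeric(1)))
}

# Pooled + normalized profile family from a planted template.
familyPool <- function(template, n, seed, poolWindow = 8L, ...) {
  X <- plantedMotifDataset(template, nProfiles = n, seed = seed,
                           poolWindow = poolWindow, ...)
  normalizeProfiles(poolProfiles(X, poolWindow))
}

# Random SAX segment sets in three regimes: uniform, jittered families,
# bounded random walks.
randomSegmentSet <- function(n, L = 32L, alphabetSize = 24L, regime = 0L) {
  a <- alphabetSize - 1L
  if (regime == 0L) return(matrix(sample(0:a, n * L, TRUE), n))
  if (regime == 1L) {
    f <- sample(2:5, 1)
    base <- matrix(sample(0:a, f * L, TRUE), f)
    return(t(vapply(seq_len(n), function(i)
      pmin(pmax(base[sample(f, 1), ] + sample(-1:1, L, TRUE), 0L), a),
      integer(L))))
  }
  t(vapply(seq_len(n), function(i) {
    w <- cumsum(c(sample(0:a, 1), sample(-2:2, L - 1L, TRUE)))
    as.integer(pmin(pmax(w, 0), a))
  }, integer(L)))
}

# Deterministic all-homozygous deletion training cohort written to `dir`:
# nSamples tracks sharing nDels window-sized deletions, plus VCF + metadata.
writeDelCohort <- function(dir, nSamples = 5L, seed = 1L,
                           contigLength = 35000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  starts <- c(3000L, 8000L, 13000L, 18000L, 23000L, 28000L)
  lens <- c(1500L, 2000L, 1200L, 2500L, 1800L, 1400L)
  vs <- data.frame(variantId = paste0("var", seq_along(starts)),
                   contig = "chr1", start = starts, svtype = "DEL",
                   filter = "PASS", length = lens,
                   end = starts + lens - 1L)
  samples <- sprintf("S%02d", seq_len(nSamples))
  gt <- matrix("1/1", nrow(vs), nSamples,
               dimnames = list(vs$variantId, samples))
  meta <- list()
  withr::with_seed(seed, {
    for (s in samples) {
      ev <- data.frame(svtype = vs$svtype, start = vs$start,
                       length = vs$length, genotype = "HOM_ALT")
      sim <- simulateSample(simSpec(contigLength, ev),
                            seed = sample.int(1e6, 1), sampleId = s)
      writeBcov(sim$track, file.path(dir, paste0(s, ".bcov")))
      meta[[s]] <- data.frame(sample_id = s, population = "SYN", sex = "U",
                              mean_coverage = sim$stats[["mean"]],
                              sd_coverage = sim$stats[["sd"]],
                              bcov_path = paste0(s, ".bcov"))
    }
  })
  writeSvVcf(vs, gt, file.path(dir, "dels.vcf"),
             contigLengths = c(chr1 = contigLength))
  utils::write.table(do.call(rbind, meta), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(vcf = file.path(dir, "dels.vcf"),
       meta = file.path(dir, "metadata.tsv"),
       bcov = stats::setNames(file.path(dir, paste0(samples, ".bcov")), samples),
       variants = vs, gt = gt)
}
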