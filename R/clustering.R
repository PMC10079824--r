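.dbaBarycenter <- function(members, init, iter = 5L, band = -1L) {
  b <- init
  L <- length(b)
  for (it in seq_len(iter)) {
    sums <- numeric(L); counts <- numeric(L)
    for (i in seq_len(nrow(members))) {
      path <- cpp_dtw_path(members[i, ], b, band)
      sums <- sums + unname(tapply(members[i, path[, 1L]], path[, 2L], sum)[as.character(seq_len(L))])
      counts <- counts + unname(table(factor(path[, 2L], levels = seq_len(L))))
    }
    newB <- sums / counts
    if (max(abs(newB - b)) < 1e-10) { b <- newB; break }
    b <- newB
  }
  b
}

.kmeansPlusPlusInit <- function(X, k, band) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- cpp_dtw_many(X, X[centers[1L], ], band)^2
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, cpp_dtw_many(X, X[centers[j], ], band)^2)
    }
  }
  X[centers, , drop = FALSE]
}

.dtwAssign <- function(X, centers, band) {
  D <- vapply(seq_len(nrow(centers)),
              function(j) cpp_dtw_many(X, centers[j, ], band),
              numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X))
  list(labels = max.col(-D, ties.method = "first"),
       inertia = sum(D[cbind(seq_len(nrow(X)), max.col(-D, ties.method = "first"))]^2))
}

#' DTW K-means clustering with barycenter averaging
#'
#' K-means over equal-length profiles under dynamic-time-warping distance:
#' k-means++-style seeding on DTW distances, assignment to the nearest
#' barycenter, and DTW barycenter averaging (DBA) updates. The run is
#' deterministic for a given seed; several restarts are performed and the
#' solution with the lowest inertia (sum of squared DTW distances) is kept.
#' The recorded objective trace of the winning restart is non-increasing.
#'
#' @param X Numeric matrix, one profile per row.
#' @param k Number of clusters (`1 <= k <= nrow(X)`).
#' @param seed Random seed.
#' @param restarts Number of random restarts.
#' @param maxIter Iteration cap per restart.
#' @param dbaIter Barycenter-averaging iterations per update.
#' @param band Sakoe-Chiba band (`NULL`/`NA` = unconstrained).
#' @return A [DTWKMeansModel-class].
#' @export
dtwKmeans <- function(X, k, seed = 1L, restarts = 10L, maxIter = 15L,
                      dbaIter = 5L, band = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) svwStop("svw_validation", "fewer profiles than clusters")
  band <- as.integer(band %||% -1L)
  if (k == 1L) {
    b <- .dbaBarycenter(X, colMeans(X), iter = dbaIter, band = band)
    d <- cpp_dtw_many(X, b, band)
    return(new("DTWKMeansModel", k = 1L,
               barycenters = matrix(b, nrow = 1L),
               labels = rep(1L, n), inertia = sum(d^2),
               objectiveTrace = sum(d^2)))
  }
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      centers <- .kmeansPlusPlusInit(X, k, band)
      trace <- numeric(0)
      labels <- integer(n)
      for (it in seq_len(maxIter)) {
        a <- .dtwAssign(X, centers, band)
        trace <- c(trace, a$inertia)
        if (it > 1L && identical(a$labels, labels)) { labels <- a$labels; break }
        labels <- a$labels
        for (j in seq_len(k)) {
          members <- X[labels == j, , drop = FALSE]
          if (nrow(members) == 0L) next
          init <- if (nrow(members) == 1L) members[1L, ] else centers[j, ]
          centers[j, ] <- .dbaBarycenter(members, init, iter = dbaIter,
                                         band = band)
        }
        a2 <- .dtwAssign(X, centers, band)
        trace <- c(trace, a2$inertia)
      }
      final <- .dtwAssign(X, centers, band)
      if (is.null(best) || final$inertia < best$inertia) {
        best <- list(centers = centers, labels = final$labels,
                     inertia = final$inertia, trace = trace)
      }
    }
  })
  new("DTWKMeansModel", k = as.integer(k), barycenters = best$centers,
      labels = as.integer(best$labels), inertia = best$inertia,
      objectiveTrace = best$trace)
}

#' Cluster-assignment agreement up to label permutation
#'
#' Fraction of items assigned consistently between two clusterings,
#' maximised over all permutations of the label alphabet; symmetric in its
#' two arguments and invariant to relabelling either clustering.
#'
#' @param a,b Equal-length label vectors.
#' @return Agreement in `[0, 1]`.
#' @export
clusterAgreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- sort(unique(a)); lb <- sort(unique(b))
  k <- max(length(la), length(lb))
  if (k > 6L) stop("agreement by permutation is limited to k <= 6")
  lb <- c(lb, setdiff(seq_len(k) + max(0, max(b)), lb))[seq_len(k)]
  perms <- .permutations(k)
  best <- 0
  ai <- match(a, la)
  bi <- match(b, lb)
  for (p in perms) best <- max(best, mean(p[bi] == ai, na.rm = TRUE))
  best
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L)) {
    for (pos in seq_len(k)) out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Mean silhouette of a clustering under a distance matrix
#'
#' @param D Symmetric distance matrix.
#' @param labels Integer cluster labels (1-based).
#' @return Mean silhouette width.
#' @export
silhouetteMean <- function(D, labels) {
  sil <- cluster::silhouette(labels, dmatrix = as.matrix(D))
  mean(sil[, "sil_width"])
}

#' Estimate the number of clusters by silhouette bootstrap
#'
#' Repeatedly subsamples the profile pool without replacement, clusters each
#' subsample at every candidate `k` with [dtwKmeans()], scores the partition
#' by mean silhouette under DTW distance, and returns the `k` with the
#' highest mean silhouette across runs. On breakpoint coverage data this
#' analysis supports `k = 2`: finer partitions are not justified.
#'
#' @param X Profile matrix (rows).
#' @param ks Candidate cluster counts (integers >= 2).
#' @param runs Number of subsampling runs.
#' @param subsetSize Profiles per run (without replacement).
#' @param seed Random seed.
#' @param config An [SVWaveConfig-class] supplying the K-means controls.
#' @return The selected `k`. The per-k mean silhouettes are attached as
#'   attribute `"silhouette"`.
#' @export
estimateK <- function(X, ks = 2:4, runs = 80L, subsetSize = 100L, seed = 1L,
                      config = SVWaveConfig()) {
  X <- as.matrix(X)
  stopifnot(all(ks >= 2), runs >= 1)
  if (nrow(X) < subsetSize)
    svwStop("svw_validation", "profile pool smaller than the subsample size")
  band <- config@band %||% -1L
  scores <- matrix(NA_real_, nrow = runs, ncol = length(ks))
  withSeed(seed, {
    for (r in seq_len(runs)) {
      idx <- sample.int(nrow(X), subsetSize)
      S <- X[idx, , drop = FALSE]
      D <- cpp_dtw_pairwise(S, as.integer(band))
      for (j in seq_along(ks)) {
        km <- dtwKmeans(S, ks[j], seed = sample.int(1e6, 1L),
                        restarts = config@kmRestarts, maxIter = config@kmMaxIter,
                        dbaIter = config@dbaIter, band = config@band)
        scores[r, j] <- silhouetteMean(D, clusterLabels(km))
      }
    }
  })
  meanSil <- colMeans(scores)
  out <- ks[which.max(meanSil)]
  attr(out, "silhouette") <- stats::setNames(meanSil, ks)
  out
}

#' Compression-consistency experiment
#'
#' Quantifies how much signal compression perturbs clustering relative to
#' the perturbation caused by the random seed alone. Per repeat, a random
#' subset of raw profiles is drawn; `C0` and `C1` cluster the pooled
#' (compressed) profiles under two different seeds, `C2` clusters the
#' uncompressed profiles under `C0`'s seed. The agreement (label-permutation
#' maximum) between `C0` and `C1` is the seed effect; between `C0` and `C2`
#' the compression effect. The two agreement distributions are compared with
#' a one-sided two-sample Kolmogorov-Smirnov test of the alternative that
#' seed-effect agreements are stochastically smaller than compression-effect
#' agreements.
#'
#' @param X Raw (uncompressed) profile matrix, profiles in rows.
#' @param repeats Number of repeats.
#' @param subsetSize Profiles drawn per repeat.
#' @param poolWindow Average-pooling window used for the compressed arm.
#' @param seed Random seed.
#' @param config An [SVWaveConfig-class] (K-means controls and `kClusters`).
#' @return List with `seedEffect` and `compressionEffect` (per-repeat
#'   agreement percentages), `ks_statistic` and `p_value`.
#' @export
consistencyValidation <- function(X, repeats = 80L, subsetSize = 100L,
                                  poolWindow = 8L, seed = 1L,
                                  config = SVWaveConfig()) {
  X <- as.matrix(X)
  if (nrow(X) < subsetSize)
    svwStop("svw_validation", "pool smaller than subsetSize")
  seedEff <- numeric(repeats); compEff <- numeric(repeats)
  withSeed(seed, {
    for (r in seq_len(repeats)) {
      idx <- sample.int(nrow(X), subsetSize)
      raw <- X[idx, , drop = FALSE]
      comp <- normalizeProfiles(poolProfiles(raw, poolWindow))
      unc <- normalizeProfiles(raw)
      seedA <- sample.int(1e6, 1L); seedB <- sample.int(1e6, 1L)
      km <- function(M, s) dtwKmeans(M, config@kClusters, seed = s,
                                     restarts = config@kmRestarts,
                                     maxIter = config@kmMaxIter,
                                     dbaIter = config@dbaIter,
                                     band = config@band)
      C0 <- clusterLabels(km(comp, seedA))
      C1 <- clusterLabels(km(comp, seedB))
      C2 <- clusterLabels(km(unc, seedA))
      seedEff[r] <- 100 * clusterAgreement(C0, C1)
      compEff[r] <- 100 * clusterAgreement(C0, C2)
    }
  })
  ks <- suppressWarnings(stats::ks.test(seedEff, compEff, alternative = "greater"))
  list(seedEffect = seedEff, compressionEffect = compEff,
       ks_statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Write the consistency report
#'
#' TSV of the two per-repeat agreement distributions plus a density plot.
#'
#' @param result Output of [consistencyValidation()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
writeConsistencyReport <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(repeat_id = seq_along(result$seedEffect),
                   seed_effect = result$seedEffect,
                   compression_effect = result$compressionEffect)
  utils::write.table(df, file.path(dir, "consistency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grDevices::pdf(file.path(dir, "consistency.pdf"), width = 6, height = 4)
  on.exit(grDevices::dev.off())
  rng <- range(c(result$seedEffect, result$compressionEffect))
  graphics::hist(result$seedEffect, breaks = 10,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlim = c(max(0, rng[1] - 5), 100), freq = FALSE,
                 main = "Clustering consistency", xlab = "agreement (%)")
  graphics::hist(result$compressionEffect, breaks = 10,
                 col = grDevices::adjustcolor("tomato", 0.5), freq = FALSE,
                 add = TRUE)
  graphics::legend("topleft", fill = c("steelblue", "tomato"),
                   legend = c("seed effect (C0 vs C1)",
                              "compression effect (C0 vs C2)"), bty = "n")
  invisible(dir)
}
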