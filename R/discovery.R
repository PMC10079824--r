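#' Fixed reference nodes for the pruned segment search
#'
#' The two 1D projection axes of the modified nearest-neighbour search are
#' distances to fixed reference words: the SAX transforms of z-normalized
#' sine and cosine sampled at `segLen` equispaced points on `[0, pi/2]`. Sine
#' gives a monotonically non-decreasing word, cosine a non-increasing one;
#' the construction is fully deterministic.
#'
#' @param segLen Segment length in symbols (>= 2).
#' @param alphabetSize SAX alphabet size.
#' @return List with integer words `sin` and `cos`.
#' @export
makeReferences <- function(segLen, alphabetSize) {
  stopifnot(segLen >= 2)
  t <- seq(0, pi / 2, length.out = segLen)
  list(sin = saxTransform(normalizeProfile(sin(t)), alphabetSize),
       cos = saxTransform(normalizeProfile(cos(t)), alphabetSize))
}

# Word-to-reference SAX distances for all rows of a word matrix.
.mindistToRef <- function(words, ref, tab, scale) {
  n <- nrow(words); L <- ncol(words)
  cells <- tab[cbind(as.vector(words) + 1L, rep(ref + 1L, each = n))]
  scale * sqrt(rowSums(matrix(cells^2, nrow = n)))
}

#' Per-position exactness slack of the 1D projection filter
#'
#' The SAX distance is not a metric (adjacent symbols are at distance zero),
#' so projecting words onto their distances from a reference can shift two
#' close words apart by more than their distance. The shift is bounded: per
#' position it cannot exceed
#' `max over symbol pairs (r, c) of [max_s |cell(r, s) - cell(c, s)| -
#' cell(r, c)]`, computed here exhaustively for the alphabet. Widening the 1D
#' candidate window by `sqrt(n/w) * sqrt(segLen)` times this value therefore
#' makes the pruned search provably equal to the brute-force grouping.
#'
#' @param alphabetSize Alphabet size.
#' @return Non-negative per-position slack.
#' @export
knnProjectionSlack <- function(alphabetSize) {
  key <- paste0("slack", alphabetSize)
  if (!is.null(.saxCache[[key]])) return(.saxCache[[key]])
  tab <- saxCellTable(alphabetSize)
  a <- as.integer(alphabetSize)
  viol <- 0
  for (r in seq_len(a)) for (cc in seq_len(a)) {
    if (r == cc) next
    viol <- max(viol, max(abs(tab[r, ] - tab[cc, ])) - tab[r, cc])
  }
  .saxCache[[key]] <- viol
  viol
}

#' Reference-point-pruned similarity-group search over SAX segments
#'
#' The core motif-discovery step. Every segment is projected onto two 1D
#' axes: its SAX distance `S_i` to the sine reference and `C_i` to the
#' cosine reference. A pair is a candidate only when both projections are
#' close (`|S_i - S_j|` and `|C_i - C_j|` within the candidate window); the
#' full SAX distance is computed for candidates alone, and pairs within
#' `eps` are linked. Similarity groups are the single-linkage components of
#' the resulting graph, ranked by size (prominence) with ties broken by
#' smaller mean intra-group distance. With `exact = TRUE` (default) the
#' candidate window is `eps` plus the [knnProjectionSlack()] bound, which
#' guarantees the grouping equals an all-pairs search.
#'
#' @param segments Integer matrix of segments (rows; 0-based symbols), as
#'   produced by [segmentSliding()]; an `"offsets"` attribute and/or
#'   `"profile"` attribute (per-row provenance) is carried into the groups.
#' @param refs Reference nodes from [makeReferences()].
#' @param eps Neighbourhood threshold on the SAX distance (>= 0).
#' @param originalLength Pre-SAX length each segment summarises (scaling of
#'   the SAX distance).
#' @param alphabetSize Alphabet size.
#' @param exact Apply the exactness slack to the candidate window.
#' @return List of class `svwSimilarityGroups`: per group (in rank order)
#'   `members` (row indices), `size`, `representative` (the central member:
#'   the member word closest to the group's positional mean), `repMember`
#'   (its row index), `meanIntra`, `rank`; attributes `n_eval` (full
#'   distance evaluations performed) and `eps`.
#' @export
knnSearchModified <- function(segments, refs, eps, originalLength,
                              alphabetSize, exact = TRUE) {
  if (eps < 0) svwStop("svw_validation", "eps must be >= 0")
  words <- as.matrix(segments)
  n <- nrow(words); L <- ncol(words)
  if (L != length(refs$sin))
    svwStop("svw_validation", "segment length does not match the references")
  tab <- saxCellTable(alphabetSize)
  scale <- sqrt(originalLength / L)
  S <- .mindistToRef(words, refs$sin, tab, scale)
  C <- .mindistToRef(words, refs$cos, tab, scale)
  slack <- if (exact) scale * sqrt(L) * knnProjectionSlack(alphabetSize) else 0
  res <- cpp_knn_groups(words, tab^2, scale, S, C, eps + slack, eps)
  labels <- res$labels + 1L
  groups <- split(seq_len(n), labels)
  sizes <- lengths(groups)
  # mean intra-group SAX distance, needed only to break prominence ties
  meanIntra <- rep(NA_real_, length(groups))
  tied <- sizes %in% sizes[duplicated(sizes)]
  for (g in seq_along(groups)) {
    if (sizes[g] == 1L) { meanIntra[g] <- 0; next }
    if (!tied[g]) next
    ix <- groups[[g]]
    W <- words[ix, , drop = FALSE]
    D2 <- matrix(0, length(ix), length(ix))
    for (p in seq_len(L)) {
      cp <- tab[W[, p] + 1L, W[, p] + 1L]
      D2 <- D2 + cp^2
    }
    meanIntra[g] <- mean(scale * sqrt(D2[upper.tri(D2)]))
  }
  ord <- order(-sizes, ifelse(is.na(meanIntra), 0, meanIntra))
  out <- vector("list", length(groups))
  for (r in seq_along(ord)) {
    g <- ord[r]
    ix <- groups[[g]]
    # representative: the central member - the member word closest (in SAX
    # distance) to the group's positional mean. Averaging the members
    # directly would blur shift-related variation within a single-linkage
    # group into a waveform no member actually has; the central member keeps
    # an observed waveform and carries its own origin offset.
    W <- words[ix, , drop = FALSE]
    ctr <- colMeans(W)
    dev <- rowSums((W - rep(ctr, each = nrow(W)))^2)
    repMember <- ix[which.min(dev)]
    out[[r]] <- list(members = ix, size = sizes[[g]],
                     representative = words[repMember, ],
                     repMember = repMember,
                     meanIntra = meanIntra[g], rank = r)
  }
  structure(out, class = "svwSimilarityGroups",
            n_eval = res$n_eval, eps = eps)
}

#' Calibrate the neighbourhood threshold
#'
#' The search threshold `eps` is calibrated as the 5th percentile of the
#' pairwise SAX distances over a sample of segments, so roughly the closest
#' 5 percent of segment pairs fall inside a neighbourhood.
#'
#' @param segments Segment matrix.
#' @param originalLength,alphabetSize As in [knnSearchModified()].
#' @param maxSample Cap on the number of segments used.
#' @param probs Percentile (default 0.05).
#' @return The calibrated `eps`.
#' @export
calibrateEps <- function(segments, originalLength, alphabetSize,
                         maxSample = 400L, probs = 0.05) {
  words <- as.matrix(segments)
  if (nrow(words) > maxSample)
    words <- words[seq(1L, nrow(words), length.out = maxSample), , drop = FALSE]
  tab <- saxCellTable(alphabetSize)
  L <- ncol(words)
  D2 <- matrix(0, nrow(words), nrow(words))
  for (p in seq_len(L)) {
    cp <- tab[words[, p] + 1L, words[, p] + 1L]
    D2 <- D2 + cp^2
  }
  d <- sqrt(originalLength / L) * sqrt(D2[upper.tri(D2)])
  unname(stats::quantile(d, probs))
}

#' Restrict motif discovery to the representative cluster
#'
#' When the larger of the two clusters holds strictly more than
#' `thresholdShare` percent of the profiles, discovery is restricted to it;
#' otherwise both clusters are searched (the typical signature of ambiguous
#' breakpoints).
#'
#' @param model A [DTWKMeansModel-class] with `k = 2`, or an integer label
#'   vector.
#' @param thresholdShare Percent threshold (strictly-greater rule).
#' @return Integer vector of selected cluster ids (1-based), ordered by
#'   decreasing cluster size.
#' @export
selectClusterScope <- function(model, thresholdShare = 66) {
  labels <- if (is(model, "DTWKMeansModel")) clusterLabels(model) else as.integer(model)
  k <- max(labels)
  sizes <- tabulate(labels, k)
  top <- which.max(sizes)
  if (100 * sizes[top] / length(labels) > thresholdShare) return(top)
  order(sizes, decreasing = TRUE)
}

#' Bootstrap motif discovery over a profile pool
#'
#' Runs the per-subset discovery pipeline `nBootstrap` times: draw
#' `bootstrapSize` profiles (without replacement when the pool is large
#' enough, with replacement otherwise), pool by `poolWindow`, normalize,
#' cluster into `kClusters` by DTW K-means, restrict to the representative
#' cluster when one exists, SAX-transform the cluster members, cut sliding
#' segments, and group them with [knnSearchModified()]. Each subset emits the
#' top-ranked group's representative per searched cluster, together with the
#' group's size and the anchor (the breakpoint's pooled offset within the
#' segment, inferred from the member segments' origins).
#'
#' @param X Raw profile matrix (profiles in rows, length `2 * halfWidth`).
#' @param config An [SVWaveConfig-class].
#' @param seed Random seed.
#' @param stats Optional per-profile sample moments for normalization.
#' @return `data.frame` of per-subset candidates: `subset`, `clusterRank`
#'   (1 = larger cluster), `share` (cluster share, %), `sax`, `support`
#'   (group size), `anchor`, `nSegments`, `nEval`. The calibrated `eps` is
#'   attached as attribute `"eps"`.
#' @export
bootstrapDiscover <- function(X, config = SVWaveConfig(), seed = 1L,
                              stats = NULL) {
  X <- as.matrix(X)
  if (!nrow(X)) svwStop("svw_validation", "empty profile pool")
  pw <- config@poolWindow
  segLen <- config@segLen
  originalLength <- segLen * pw
  refs <- makeReferences(segLen, config@alphabetSize)
  anchorOffset <- config@halfWidth %/% pw   # breakpoint's pooled offset
  # calibrate eps once, on segments from a deterministic sample of the pool
  eps <- config@eps
  withSeed(seed, {
    if (is.na(eps)) {
      idx <- sample.int(nrow(X), min(nrow(X), 100L))
      pooled <- normalizeProfiles(poolProfiles(X[idx, , drop = FALSE], pw),
                                  if (is.null(stats)) NULL else stats[idx, , drop = FALSE])
      segs <- do.call(rbind, lapply(seq_len(nrow(pooled)), function(i)
        segmentSliding(saxTransform(pooled[i, ], config@alphabetSize),
                       segLen, config@slidingStep)))
      eps <- calibrateEps(segs, originalLength, config@alphabetSize)
    }
    replace <- nrow(X) < config@bootstrapSize
    if (replace)
      message("pool (", nrow(X), ") smaller than bootstrapSize (",
              config@bootstrapSize, "); sampling with replacement")
    rows <- list()
    for (b in seq_len(config@nBootstrap)) {
      idx <- sample.int(nrow(X), config@bootstrapSize, replace = replace)
      raw <- X[idx, , drop = FALSE]
      norm <- normalizeProfiles(poolProfiles(raw, pw),
                                if (is.null(stats)) NULL else stats[idx, , drop = FALSE])
      km <- dtwKmeans(norm, config@kClusters, seed = sample.int(1e6, 1L),
                      restarts = config@kmRestarts, maxIter = config@kmMaxIter,
                      dbaIter = config@dbaIter, band = config@band)
      scope <- selectClusterScope(km, config@representativeShare)
      labels <- clusterLabels(km)
      for (cr in seq_along(scope)) {
        cl <- scope[cr]
        members <- which(labels == cl)
        if (length(members) < 2L) next
        segList <- lapply(members, function(i)
          segmentSliding(saxTransform(norm[i, ], config@alphabetSize),
                         segLen, config@slidingStep))
        offsets <- unlist(lapply(segList, attr, "offsets"))
        segs <- do.call(rbind, segList)
        groups <- knnSearchModified(segs, refs, eps, originalLength,
                                    config@alphabetSize,
                                    exact = config@knnExact)
        top <- groups[[1L]]
        anchor <- anchorOffset - offsets[top$repMember]
        rows[[length(rows) + 1L]] <- data.frame(
          subset = b, clusterRank = cr,
          share = 100 * length(members) / length(labels),
          sax = saxToString(top$representative, config@alphabetSize),
          support = top$size, anchor = anchor,
          nSegments = nrow(segs), nEval = attr(groups, "n_eval"))
      }
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "eps") <- eps
  out
}

#' Merge bootstrap motif candidates into a predominant motif
#'
#' Iterative agglomeration of candidate SAX words: while any pair of
#' representatives lies within `mergeEps` in SAX distance, the closest pair
#' is merged; the merged word is the per-position support-weighted mean of
#' the symbol indices, rounded half to even, and supports add. The
#' representative of the largest merged family is the predominant motif.
#'
#' @param candidates Character vector of SAX words (or the `data.frame` from
#'   [bootstrapDiscover()], whose `sax`, `support` and `anchor` columns are
#'   used).
#' @param mergeEps Merge threshold on the SAX distance.
#' @param originalLength,alphabetSize As in [saxMindist()].
#' @param support Optional supports (default 1 each).
#' @param anchor Optional anchors, averaged with the same weights.
#' @return List: `sax` (string), `symbols`, `support`, `anchor`,
#'   `nFamilies`, `familySupports`.
#' @export
mergeMotifs <- function(candidates, mergeEps, originalLength, alphabetSize,
                        support = NULL, anchor = NULL) {
  if (is.data.frame(candidates)) {
    support <- support %||% candidates$support
    anchor <- anchor %||% candidates$anchor
    candidates <- candidates$sax
  }
  if (!length(candidates)) svwStop("svw_validation", "no candidates to merge")
  words <- lapply(candidates, stringToSax, alphabetSize = alphabetSize)
  support <- as.numeric(support %||% rep(1, length(words)))
  anchor <- as.numeric(anchor %||% rep(NA_real_, length(words)))
  original <- list(words = words, support = support, anchor = anchor)
  members <- as.list(seq_along(words))
  m <- length(words)
  D <- matrix(Inf, m, m)
  if (m > 1L) for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    D[i, j] <- saxMindist(words[[i]], words[[j]], originalLength, alphabetSize)
  while (length(words) > 1L && min(D) <= mergeEps) {
    ij <- which(D == min(D), arr.ind = TRUE)[1L, ]   # deterministic: first pair
    i <- ij[[1L]]; j <- ij[[2L]]
    wsum <- support[i] + support[j]
    merged <- as.integer(round((support[i] * words[[i]] +
                                support[j] * words[[j]]) / wsum))
    anchors <- c(anchor[i], anchor[j]); w <- c(support[i], support[j])
    mergedAnchor <- if (all(is.na(anchors))) NA_real_
      else round(sum(w[!is.na(anchors)] * anchors[!is.na(anchors)]) /
                 sum(w[!is.na(anchors)]))
    words[[i]] <- merged; support[i] <- wsum; anchor[i] <- mergedAnchor
    members[[i]] <- c(members[[i]], members[[j]])
    words[[j]] <- NULL; support <- support[-j]; anchor <- anchor[-j]
    members[[j]] <- NULL
    D <- D[-j, -j, drop = FALSE]
    if (length(words) > 1L) {
      for (q in seq_along(words)) {
        if (q == i) next
        d <- saxMindist(words[[i]], words[[q]], originalLength, alphabetSize)
        D[min(i, q), max(i, q)] <- d
      }
    }
  }
  top <- which.max(support)
  # final representative: one-shot support-weighted rounded mean over the
  # winning family's original candidates (a single rounding keeps less of
  # the per-candidate symbol noise than rounding at every pairwise merge)
  ix <- members[[top]]
  W <- do.call(rbind, original$words[ix])
  w <- original$support[ix]
  rep_ <- as.integer(round(colSums(W * w) / sum(w)))
  a <- original$anchor[ix]
  repAnchor <- if (all(is.na(a))) NA_real_
    else round(sum(w[!is.na(a)] * a[!is.na(a)]) / sum(w[!is.na(a)]))
  list(sax = saxToString(rep_, alphabetSize),
       symbols = rep_, support = support[top], anchor = repAnchor,
       nFamilies = length(words), familySupports = sort(support, decreasing = TRUE))
}

#' Discover predominant motifs for one profile pool
#'
#' Runs [bootstrapDiscover()] and merges the per-subset candidates (per
#' cluster rank) with [mergeMotifs()] into at most `kClusters` predominant
#' motifs. A motif whose support share (bootstraps contributing to its
#' merged family divided by the number of subsets) falls below
#' `insSupportFloor` is flagged as not convincing - the expected verdict for
#' insertion breakpoints, whose waveforms do not form a recurring shape.
#'
#' @param X Raw profile matrix (profiles in rows).
#' @param config An [SVWaveConfig-class].
#' @param seed Random seed.
#' @param stats Optional per-profile sample moments.
#' @param labels Optional named labels (`svtype`, `side`, `genotype`)
#'   attached to the output rows.
#' @return `data.frame` with one row per (cluster rank): `cluster`, `sax`,
#'   `support`, `supportShare`, `anchor`, `eps`, `convincing`, plus any
#'   label columns.
#' @export
discoverMotifs <- function(X, config = SVWaveConfig(), seed = 1L,
                           stats = NULL, labels = NULL) {
  cand <- bootstrapDiscover(X, config, seed = seed, stats = stats)
  eps <- attr(cand, "eps")
  mergeEps <- config@mergeEps %||% eps
  originalLength <- config@segLen * config@poolWindow
  rows <- lapply(sort(unique(cand$clusterRank)), function(cr) {
    cc <- cand[cand$clusterRank == cr, , drop = FALSE]
    m <- mergeMotifs(cc, mergeEps, originalLength, config@alphabetSize,
                     support = rep(1, nrow(cc)), anchor = cc$anchor)
    share <- m$support / config@nBootstrap
    data.frame(cluster = cr, sax = m$sax, support = m$support,
               supportShare = share, anchor = m$anchor, eps = eps,
               convincing = share >= config@insSupportFloor)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) for (nm in names(labels)) out[[nm]] <- labels[[nm]]
  out
}

#' Read and write motif tables
#'
#' Motif files carry the SAX word, its parameters and provenance labels, as
#' TSV (and optionally JSON alongside).
#'
#' @param motifs Motif `data.frame`.
#' @param path Output TSV path (a `.json` twin is written when
#'   `json = TRUE`).
#' @param json Also write JSON.
#' @return Invisibly, `path`.
#' @export
writeMotifs <- function(motifs, path, json = TRUE) {
  utils::write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json)
    jsonlite::write_json(motifs, sub("\\.tsv$", ".json", path),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMotifs
#' @export
readMotifs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NULL)
}
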