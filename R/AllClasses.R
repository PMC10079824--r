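#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Per-base coverage track for one contig
#'
#' Dense per-base read depth (depth of coverage, DOC) for a single contig.
#' Positions with no reads are explicit zeros, so position `i` of the contig
#' (1-based) is element `i` of the depth vector. Depths are bounded by the
#' two-byte BCOV representation, i.e. `0..65535`.
#'
#' @slot contig Single contig identifier.
#' @slot depths Integer vector of non-negative depths, one per position.
#'
#' @seealso [CoverageTrack()], [writeBcov()], [sliceWindow()]
#' @export
setClass("CoverageTrack",
  representation(contig = "character", depths = "integer"))

setValidity("CoverageTrack", function(object) {
  msg <- NULL
  if (length(object@contig) != 1L || is.na(object@contig) || !nzchar(object@contig))
    msg <- c(msg, "'contig' must be a single non-empty string")
  d <- object@depths
  if (anyNA(d)) msg <- c(msg, "depths must not contain NA")
  else {
    if (length(d) && min(d) < 0L) msg <- c(msg, "depths must be non-negative")
    if (length(d) && max(d) > 65535L)
      msg <- c(msg, "depths exceed the two-byte maximum (65535)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CoverageTrack
#'
#' @param contig Contig name.
#' @param depths Non-negative integer depths (numeric vectors are accepted if
#'   they hold whole numbers). Values above 65535 are an error here; clamping
#'   is a property of the BCOV *encoder*, not of the in-memory container.
#' @return A [CoverageTrack-class] object.
#' @examples
#' tr <- CoverageTrack("chr1", c(0, 3, 5, 5, 2))
#' trackLength(tr)
#' @export
CoverageTrack <- function(contig, depths) {
  if (is.double(depths)) {
    if (any(depths != floor(depths), na.rm = TRUE))
      stop("depths must be whole numbers")
    depths <- as.integer(depths)
  }
  new("CoverageTrack", contig = as.character(contig), depths = as.integer(depths))
}

setMethod("show", "CoverageTrack", function(object) {
  n <- length(object@depths)
  cat("CoverageTrack on", object@contig, "-", n, "positions\n")
  if (n) {
    cat("  mean depth:", round(mean(object@depths), 2),
        " max:", max(object@depths), "\n")
  }
})

#' Pipeline configuration
#'
#' All numeric constants of the profile-extraction and motif-discovery
#' pipeline in one validated object. Defaults correspond to short-read
#' whole-genome data at ~30x: a 512 bp breakpoint window (`halfWidth` 256),
#' 20 bp minimum SV length, 8 bp average pooling, a 24-symbol SAX alphabet,
#' 32-symbol sliding segments, two DTW K-means clusters with a 66%
#' representative-cluster rule, and 360 bootstrap subsets of 960 profiles.
#'
#' @slot halfWidth Half-width of the breakpoint window in bp (window = 2x).
#' @slot minSvLen Minimum SV length retained, bp.
#' @slot poolWindow Average-pooling window, bp.
#' @slot alphabetSize SAX alphabet size.
#' @slot segLen Sliding-segment length in SAX symbols.
#' @slot slidingStep Segment stride in symbols.
#' @slot kClusters Number of DTW K-means clusters.
#' @slot representativeShare Percent share above which motif discovery is
#'   restricted to the larger cluster (strictly greater than).
#' @slot nBootstrap Number of bootstrap subsets.
#' @slot bootstrapSize Profiles per bootstrap subset.
#' @slot consistencyRepeats Repeats of the compression-consistency experiment.
#' @slot consistencySubset Profiles per consistency repeat.
#' @slot eps Neighbourhood threshold for the segment search (NA = calibrate as
#'   the 5th percentile of pairwise SAX distances on a segment sample).
#' @slot mergeEps Motif-merging threshold (NA = same as `eps`).
#' @slot scanThreshold Scan hit threshold (NA = calibrate on motif-free
#'   synthetic coverage).
#' @slot insSupportFloor Minimum top-motif support share below which the
#'   discovery verdict is "no convincing motif".
#' @slot kmRestarts,kmMaxIter,dbaIter K-means restarts, iteration cap, and
#'   barycenter-averaging iterations.
#' @slot band Sakoe-Chiba DTW band (NA = unconstrained).
#' @slot knnExact Apply the exactness slack to the 1D candidate filter so the
#'   pruned search provably equals the brute-force grouping.
#' @slot seed Base random seed for all stochastic stages.
#' @export
setClass("SVWaveConfig",
  representation(
    halfWidth = "integer", minSvLen = "integer", poolWindow = "integer",
    alphabetSize = "integer", segLen = "integer", slidingStep = "integer",
    kClusters = "integer", representativeShare = "numeric",
    nBootstrap = "integer", bootstrapSize = "integer",
    consistencyRepeats = "integer", consistencySubset = "integer",
    eps = "numeric", mergeEps = "numeric", scanThreshold = "numeric",
    insSupportFloor = "numeric",
    kmRestarts = "integer", kmMaxIter = "integer", dbaIter = "integer",
    band = "integer", knnExact = "logical", seed = "integer"))

setValidity("SVWaveConfig", function(object) {
  msg <- NULL
  w <- 2L * object@halfWidth
  if (object@halfWidth < 1L) msg <- c(msg, "halfWidth must be >= 1")
  if (object@poolWindow < 1L) msg <- c(msg, "poolWindow must be >= 1")
  if (w %% object@poolWindow != 0L)
    msg <- c(msg, "window (2*halfWidth) must be divisible by poolWindow")
  if (object@segLen > w %/% object@poolWindow)
    msg <- c(msg, "segLen must not exceed the pooled profile length")
  if (object@alphabetSize < 2L) msg <- c(msg, "alphabetSize must be >= 2")
  if (object@representativeShare <= 0 || object@representativeShare >= 100)
    msg <- c(msg, "representativeShare must be in (0, 100)")
  if (object@kClusters < 1L) msg <- c(msg, "kClusters must be >= 1")
  if (object@slidingStep < 1L) msg <- c(msg, "slidingStep must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SVWaveConfig-class
#' @param halfWidth,minSvLen,poolWindow,alphabetSize,segLen,slidingStep
#'   See the class slots.
#' @param kClusters,representativeShare,nBootstrap,bootstrapSize See slots.
#' @param consistencyRepeats,consistencySubset,eps,mergeEps,scanThreshold,
#'   insSupportFloor,kmRestarts,kmMaxIter,dbaIter,band,knnExact,seed See slots.
#' @return A validated `SVWaveConfig`.
#' @examples
#' cfg <- SVWaveConfig(seed = 7)
#' cfg
#' @export
SVWaveConfig <- function(halfWidth = 256, minSvLen = 20, poolWindow = 8,
                         alphabetSize = 24, segLen = 32, slidingStep = 1,
                         kClusters = 2, representativeShare = 66,
                         nBootstrap = 360, bootstrapSize = 960,
                         consistencyRepeats = 80, consistencySubset = 100,
                         eps = NA_real_, mergeEps = NA_real_,
                         scanThreshold = NA_real_, insSupportFloor = 0.10,
                         kmRestarts = 10, kmMaxIter = 15, dbaIter = 5,
                         band = NA_integer_, knnExact = TRUE, seed = 1L) {
  new("SVWaveConfig",
      halfWidth = as.integer(halfWidth), minSvLen = as.integer(minSvLen),
      poolWindow = as.integer(poolWindow),
      alphabetSize = as.integer(alphabetSize), segLen = as.integer(segLen),
      slidingStep = as.integer(slidingStep), kClusters = as.integer(kClusters),
      representativeShare = as.numeric(representativeShare),
      nBootstrap = as.integer(nBootstrap),
      bootstrapSize = as.integer(bootstrapSize),
      consistencyRepeats = as.integer(consistencyRepeats),
      consistencySubset = as.integer(consistencySubset),
      eps = as.numeric(eps), mergeEps = as.numeric(mergeEps),
      scanThreshold = as.numeric(scanThreshold),
      insSupportFloor = as.numeric(insSupportFloor),
      kmRestarts = as.integer(kmRestarts), kmMaxIter = as.integer(kmMaxIter),
      dbaIter = as.integer(dbaIter), band = as.integer(band),
      knnExact = as.logical(knnExact), seed = as.integer(seed))
}

setMethod("show", "SVWaveConfig", function(object) {
  cat("SVWaveConfig\n")
  cat("  window:", 2L * object@halfWidth, "bp (halfWidth", object@halfWidth,
      "), pooling:", object@poolWindow, "bp -> profile length",
      2L * object@halfWidth %/% object@poolWindow, "\n")
  cat("  SAX alphabet:", object@alphabetSize, ", segment:", object@segLen,
      "symbols, step", object@slidingStep, "\n")
  cat("  clustering: k =", object@kClusters, ", representative share >",
      object@representativeShare, "%\n")
  cat("  bootstrap:", object@nBootstrap, "subsets x", object@bootstrapSize,
      "profiles; seed", object@seed, "\n")
})

#' Breakpoint depth-of-coverage profile set
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single `"depth"`
#' assay holds one fixed-length depth window per column (profiles are
#' columns; rows are window offsets relative to the breakpoint). `colData`
#' records, per profile: `sample`, `contig`, `position` (1-based breakpoint
#' coordinate), `side` (`L`, `R`, `BP` or `spSV`), `svtype`, `genotype`
#' (`HOM_ALT` or `HET`) and `variantId`.
#'
#' @seealso [DOCProfileSet()], [extractProfiles()]
#' @export
setClass("DOCProfileSet", contains = "SummarizedExperiment")

.docRequiredCols <- c("sample", "contig", "position", "side", "svtype",
                      "genotype", "variantId")

setValidity("DOCProfileSet", function(object) {
  msg <- NULL
  if (!"depth" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'depth' is required")
  missing <- setdiff(.docRequiredCols, colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    msg <- c(msg, paste("colData lacks:", paste(missing, collapse = ", ")))
  if ("depth" %in% SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, "depth")
    if (length(a) && min(a) < 0) msg <- c(msg, "depth values must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a DOCProfileSet
#'
#' @param depth Numeric matrix, window length x number of profiles.
#' @param info `data.frame` or `DataFrame` of per-profile metadata with
#'   columns `sample`, `contig`, `position`, `side`, `svtype`, `genotype`,
#'   `variantId`.
#' @return A [DOCProfileSet-class].
#' @export
DOCProfileSet <- function(depth, info) {
  depth <- as.matrix(depth)
  info <- S4Vectors::DataFrame(info)
  if (ncol(depth) != nrow(info))
    stop("one metadata row is required per profile column")
  half <- nrow(depth) %/% 2L
  rowData <- S4Vectors::DataFrame(offset = seq_len(nrow(depth)) - half - 1L)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(depth = depth), colData = info, rowData = rowData)
  new("DOCProfileSet", se)
}

setMethod("show", "DOCProfileSet", function(object) {
  cat("DOCProfileSet:", ncol(object), "profiles of length", nrow(object), "\n")
  info <- SummarizedExperiment::colData(object)
  if (ncol(object)) {
    tb <- table(info$svtype, info$side)
    cat("  profiles per SV class / breakpoint side:\n")
    print(tb)
  }
})

#' DTW K-means model
#'
#' Result of [dtwKmeans()]: cluster count, per-cluster barycenters (rows),
#' per-profile labels (1-based), the final inertia (sum of squared DTW
#' distances to the assigned barycenter) and the objective trace, which is
#' non-increasing across assignment/update steps.
#'
#' @export
setClass("DTWKMeansModel",
  representation(k = "integer", barycenters = "matrix", labels = "integer",
                 inertia = "numeric", objectiveTrace = "numeric"))

setValidity("DTWKMeansModel", function(object) {
  msg <- NULL
  if (nrow(object@barycenters) != object@k)
    msg <- c(msg, "barycenter count must equal k")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DTWKMeansModel", function(object) {
  cat("DTWKMeansModel: k =", object@k, ",", length(object@labels),
      "profiles, inertia", signif(object@inertia, 5), "\n")
  cat("  cluster sizes:", paste(tabulate(object@labels, object@k), collapse = ", "), "\n")
})

#' Relational profile store
#'
#' File-backed relational store for extracted profiles and discovered motifs,
#' mirroring a classic sample/variant/breakpoint/profile/motif schema with
#' foreign-key validation. Serialises to a directory of TSV files
#' ([writeStore()] / [readStore()]) and supports queries by SV class,
#' genotype, breakpoint side and genomic region ([storeQuery()]).
#'
#' @slot samples `sample_id`, `population`, `sex`, `mean_coverage`,
#'   `sd_coverage`, `bcov_path`.
#' @slot variants `variant_id`, `contig`, `start`, `end`, `svtype`, `length`.
#' @slot breakpoints `breakpoint_id`, `variant_id`, `side`, `position`.
#' @slot profiles `profile_id`, `breakpoint_id`, `sample_id`, `genotype`.
#' @slot profileMatrix window length x n matrix of depths, one column per row
#'   of `profiles`.
#' @slot motifs Motif table as produced by [discoverMotifs()] (may be empty).
#' @export
setClass("ProfileStore",
  representation(samples = "data.frame", variants = "data.frame",
                 breakpoints = "data.frame", profiles = "data.frame",
                 profileMatrix = "matrix", motifs = "data.frame"))

setValidity("ProfileStore", function(object) {
  msg <- NULL
  bp <- object@breakpoints; pr <- object@profiles
  if (nrow(bp) && !all(bp$variant_id %in% object@variants$variant_id))
    msg <- c(msg, "foreign-key violation: breakpoint -> variant")
  if (nrow(pr)) {
    if (!all(pr$breakpoint_id %in% bp$breakpoint_id))
      msg <- c(msg, "foreign-key violation: profile -> breakpoint")
    if (!all(pr$sample_id %in% object@samples$sample_id))
      msg <- c(msg, "foreign-key violation: profile -> sample")
    if (ncol(object@profileMatrix) != nrow(pr))
      msg <- c(msg, "profileMatrix must have one column per profile row")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ProfileStore", function(object) {
  cat("ProfileStore:", nrow(object@samples), "samples,",
      nrow(object@variants), "variants,", nrow(object@breakpoints),
      "breakpoints,", nrow(object@profiles), "profiles,",
      nrow(object@motifs), "motifs\n")
})
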