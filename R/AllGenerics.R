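#' Track and profile accessors
#'
#' `trackContig()`/`trackDepths()`/`trackLength()` access [CoverageTrack-class]
#' slots; `profileMatrix()`/`profileInfo()` return the depth matrix and the
#' per-profile metadata of a [DOCProfileSet-class]; `clusterLabels()` and
#' `clusterCenters()` access a [DTWKMeansModel-class].
#'
#' @param x The object.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackContig", function(x) standardGeneric("trackContig"))
#' @rdname accessors
#' @export
setGeneric("trackDepths", function(x) standardGeneric("trackDepths"))
#' @rdname accessors
#' @export
setGeneric("trackLength", function(x) standardGeneric("trackLength"))
#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @rdname accessors
#' @export
setGeneric("profileInfo", function(x) standardGeneric("profileInfo"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname accessors
setMethod("trackContig", "CoverageTrack", function(x) x@contig)
#' @rdname accessors
setMethod("trackDepths", "CoverageTrack", function(x) x@depths)
#' @rdname accessors
setMethod("trackLength", "CoverageTrack", function(x) length(x@depths))
#' @rdname accessors
setMethod("profileMatrix", "DOCProfileSet",
          function(x) SummarizedExperiment::assay(x, "depth"))
#' @rdname accessors
setMethod("profileInfo", "DOCProfileSet",
          function(x) SummarizedExperiment::colData(x))
#' @rdname accessors
setMethod("clusterLabels", "DTWKMeansModel", function(x) x@labels)
#' @rdname accessors
setMethod("clusterCenters", "DTWKMeansModel", function(x) x@barycenters)

#' Slice a fixed window out of a coverage source
#'
#' Returns the `2 * halfWidth` depth values covering
#' `[center - halfWidth, center + halfWidth - 1]` in 1-based coordinates, so
#' the breakpoint sits at 0-based offset `halfWidth` of the window. Windows
#' extending past either contig end raise an out-of-bounds condition (class
#' `svw_out_of_bounds`) rather than being padded; profile extraction drops
#' such loci.
#'
#' @param x A [CoverageTrack-class], or the path to a BCOV payload written by
#'   [writeBcov()] (sliced without loading the track).
#' @param contig Contig name (checked against the track / index).
#' @param center 1-based window centre.
#' @param halfWidth Half-width in bp (window length is `2 * halfWidth`).
#' @return Integer vector of length `2 * halfWidth`.
#' @examples
#' tr <- CoverageTrack("chr1", 0:99)
#' sliceWindow(tr, "chr1", center = 50, halfWidth = 4)
#' @export
setGeneric("sliceWindow",
           function(x, contig, center, halfWidth) standardGeneric("sliceWindow"))
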