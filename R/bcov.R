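#' The BCOV lossless binary coverage format
#'
#' BCOV stores one unsigned 16-bit little-endian integer per genomic
#' position, in positional order, with no headers: a payload of exactly
#' `2 * n_positions` bytes per contig. Depths above 65535 (the two-byte
#' maximum) are clamped by the encoder. Multi-contig files concatenate the
#' per-contig payloads and describe the layout in a plain-text sidecar index
#' (`<path>.idx`, tab-separated `contig`, `byte offset`, `n positions`),
#' which makes contig lookup and window slicing O(1) seeks.
#'
#' @name bcov-format
NULL

.BCOV_MAX <- 65535L

#' Encode depths as a BCOV payload
#'
#' Low-level encoder: writes two bytes per position (little-endian unsigned
#' 16-bit) to a connection or file. Values above 65535 are clamped to 65535;
#' negative values are rejected.
#'
#' @param depths Non-negative integer depths (or a [CoverageTrack-class]).
#' @param con Writable binary connection or a file path.
#' @param append Append to `con` when it is a path.
#' @return Invisibly, the number of bytes written (`2 * length(depths)`).
#' @examples
#' f <- tempfile(fileext = ".bcov")
#' encodeBcov(c(0, 1, 2), f)
#' decodeBcov(f)
#' @export
encodeBcov <- function(depths, con, append = FALSE) {
  if (is(depths, "CoverageTrack")) depths <- trackDepths(depths)
  if (anyNA(depths)) svwStop("svw_validation", "depths must not contain NA")
  if (length(depths) && min(depths) < 0)
    svwStop("svw_validation", "depths must be non-negative")
  v <- pmin(as.integer(depths), .BCOV_MAX)
  # writeBin() writes signed 16-bit; map the upper half onto negative codes
  v <- ifelse(v > 32767L, v - 65536L, v)
  if (is.character(con)) {
    con <- file(con, if (append) "ab" else "wb")
    on.exit(close(con))
  }
  writeBin(v, con, size = 2L, endian = "little")
  invisible(2L * length(v))
}

#' Decode a BCOV payload
#'
#' Exact inverse of [encodeBcov()] for in-range depths. The payload byte
#' count must be even.
#'
#' @param src File path, binary connection, or raw vector.
#' @param n Number of positions to read (default: all).
#' @return Integer depth vector.
#' @export
decodeBcov <- function(src, n = NULL) {
  if (is.raw(src)) {
    if (length(src) %% 2L != 0L)
      svwStop("svw_format", "BCOV payload has an odd byte count")
    n <- n %||% (length(src) %/% 2L)
    return(readBin(src, "integer", n = n, size = 2L, signed = FALSE,
                   endian = "little"))
  }
  if (is.character(src)) {
    sz <- file.size(src)
    if (is.na(sz)) svwStop("svw_format", paste("no such BCOV file:", src))
    if (sz %% 2 != 0) svwStop("svw_format", "BCOV payload has an odd byte count")
    n <- n %||% (sz %/% 2)
    src <- file(src, "rb")
    on.exit(close(src))
  }
  if (is.null(n)) svwStop("svw_format", "n is required when reading a connection")
  readBin(src, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
}

#' Write coverage tracks to a BCOV file with sidecar index
#'
#' Concatenates the two-byte payloads of one or more tracks into `path` and
#' writes the plain-text index to `<path>.idx`.
#'
#' @param tracks A [CoverageTrack-class] or a list of them.
#' @param path Output payload path (conventionally `.bcov`).
#' @return Invisibly, the index `data.frame` (`contig`, `offset`, `n`).
#' @seealso [readBcov()], [readBcovIndex()], [sliceWindow()]
#' @export
writeBcov <- function(tracks, path) {
  if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
  contigs <- vapply(tracks, trackContig, character(1))
  if (anyDuplicated(contigs)) svwStop("svw_validation", "duplicate contigs")
  con <- file(path, "wb")
  on.exit(close(con))
  offset <- 0
  idx <- data.frame(contig = contigs, offset = NA_real_,
                    n = vapply(tracks, trackLength, integer(1)))
  for (i in seq_along(tracks)) {
    idx$offset[i] <- offset
    offset <- offset + encodeBcov(tracks[[i]], con)
  }
  utils::write.table(idx, paste0(path, ".idx"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(idx)
}

#' Read the sidecar index of a BCOV file
#'
#' @param path BCOV payload path (the index is `<path>.idx`).
#' @return `data.frame` with `contig`, `offset` (bytes), `n` (positions).
#' @export
readBcovIndex <- function(path) {
  idxPath <- paste0(path, ".idx")
  if (!file.exists(idxPath))
    svwStop("svw_format", paste("missing BCOV index:", idxPath))
  idx <- utils::read.table(idxPath, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "integer"))
  if (any(idx$offset %% 2 != 0))
    svwStop("svw_format", "BCOV index offsets must be even")
  if (is.unsorted(idx$offset, strictly = nrow(idx) > 1L))
    svwStop("svw_format", "BCOV index entries must be sorted by offset")
  sz <- file.size(path)
  if (!is.na(sz) && sum(2 * idx$n) != sz)
    svwStop("svw_format", "BCOV index does not account for the payload size")
  idx
}

#' Read tracks back from a BCOV file
#'
#' @param path BCOV payload path.
#' @param contig Contig to read; `NULL` reads all tracks.
#' @return A [CoverageTrack-class] (single contig) or a named list of them.
#' @export
readBcov <- function(path, contig = NULL) {
  idx <- readBcovIndex(path)
  pick <- if (is.null(contig)) seq_len(nrow(idx)) else match(contig, idx$contig)
  if (anyNA(pick))
    svwStop("svw_lookup", paste("contig not in BCOV index:", contig))
  con <- file(path, "rb")
  on.exit(close(con))
  out <- lapply(pick, function(i) {
    seek(con, idx$offset[i])
    CoverageTrack(idx$contig[i], decodeBcov(con, n = idx$n[i]))
  })
  if (!is.null(contig) && length(out) == 1L) out[[1]]
  else stats::setNames(out, idx$contig[pick])
}

.checkWindow <- function(center, halfWidth, len, contig) {
  if (halfWidth < 1) svwStop("svw_validation", "halfWidth must be >= 1")
  lo <- center - halfWidth
  hi <- center + halfWidth - 1
  if (lo < 1 || hi > len)
    svwStop("svw_out_of_bounds",
            sprintf("window [%d, %d] exceeds contig %s (length %d)",
                    lo, hi, contig, len))
  c(lo, hi)
}

#' @rdname sliceWindow
setMethod("sliceWindow", "CoverageTrack", function(x, contig, center, halfWidth) {
  if (!identical(contig, trackContig(x)))
    svwStop("svw_lookup", paste("track is not", contig))
  w <- .checkWindow(center, halfWidth, trackLength(x), contig)
  trackDepths(x)[w[1]:w[2]]
})

#' @rdname sliceWindow
setMethod("sliceWindow", "character", function(x, contig, center, halfWidth) {
  idx <- readBcovIndex(x)
  i <- match(contig, idx$contig)
  if (is.na(i)) svwStop("svw_lookup", paste("contig not in BCOV index:", contig))
  w <- .checkWindow(center, halfWidth, idx$n[i], contig)
  con <- file(x, "rb")
  on.exit(close(con))
  seek(con, idx$offset[i] + 2 * (w[1] - 1))
  decodeBcov(con, n = 2L * halfWidth)
})

#' Densify bedGraph coverage into per-contig tracks
#'
#' Reads standard bedGraph (0-based, half-open intervals) and expands it into
#' dense [CoverageTrack-class] objects, one per declared contig; uncovered
#' positions become explicit zeros. Overlapping intervals and intervals
#' beyond the declared contig length are format errors.
#'
#' @param path bedGraph file.
#' @param contigLengths Named integer vector of contig lengths.
#' @return Named list of [CoverageTrack-class] objects (one per name in
#'   `contigLengths`).
#' @export
bedgraphToTracks <- function(path, contigLengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(contigLengths), function(ctg) {
    len <- as.integer(contigLengths[[ctg]])
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ctg]
    depths <- integer(len)
    if (length(g)) {
      g <- g[order(GenomicRanges::start(g))]
      s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
      if (any(e > len))
        svwStop("svw_format", sprintf("interval beyond contig %s length %d", ctg, len))
      if (length(g) > 1L && any(s[-1] <= e[-length(e)]))
        svwStop("svw_format", sprintf("overlapping bedGraph intervals on %s", ctg))
      for (i in seq_along(g)) depths[s[i]:e[i]] <- g$score[i]
    }
    CoverageTrack(ctg, depths)
  })
  stats::setNames(out, names(contigLengths))
}

#' Write a track as bedGraph
#'
#' Run-length encodes the dense depths and exports standard bedGraph
#' (0-based, half-open), the interchange format the simulator and converter
#' round-trip through.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
trackToBedgraph <- function(track, path) {
  r <- S4Vectors::Rle(trackDepths(track))
  ends <- cumsum(S4Vectors::runLength(r))
  starts <- ends - S4Vectors::runLength(r) + 1L
  gr <- GenomicRanges::GRanges(trackContig(track),
                               IRanges::IRanges(starts, ends),
                               score = S4Vectors::runValue(r))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
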