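.motifSymbols <- function(motif, alphabetSize) {
  if (is.character(motif)) stringToSax(motif, alphabetSize) else as.integer(motif)
}

#' Scan one depth profile for a motif
#'
#' Applies the discovery preprocessing to the profile (average pooling,
#' z-normalization, SAX) and evaluates the SAX distance between the motif
#' word and every `segLen`-symbol window of the profile word. Offsets are
#' 0-based in pooled units; multiply by `poolWindow` for bp. With a
#' `threshold`, only offsets scoring at or below it are returned, sorted by
#' score ascending.
#'
#' @param profile Numeric depth vector (length >= `segLen * poolWindow`).
#' @param motif Motif SAX word (string or 0-based integer vector).
#' @param config An [SVWaveConfig-class].
#' @param threshold Score cutoff; `NULL` returns all offsets.
#' @param stats Optional sample moments (mean, sd) for normalization.
#' @return `data.frame` with `offset` and `score`.
#' @export
scanProfile <- function(profile, motif, config = SVWaveConfig(),
                        threshold = NULL, stats = NULL) {
  pw <- config@poolWindow
  segLen <- config@segLen
  sym <- .motifSymbols(motif, config@alphabetSize)
  if (length(sym) != segLen)
    svwStop("svw_validation", "motif length does not match config segLen")
  if (length(profile) < segLen * pw) {
    message("profile shorter than one motif instance; no scan")
    return(data.frame(offset = integer(0), score = numeric(0)))
  }
  pooled <- poolAverage(profile, pw)
  norm <- if (is.null(stats)) normalizeProfile(pooled)
          else normalizeProfile(pooled, stats[1L], stats[2L])
  word <- saxTransform(norm, config@alphabetSize)
  scale <- sqrt(segLen * pw / segLen)
  scores <- cpp_scan_word(word, sym, saxCellTable(config@alphabetSize)^2, scale)
  out <- data.frame(offset = seq_along(scores) - 1L, score = scores)
  if (!is.null(threshold)) out <- out[out$score <= threshold, , drop = FALSE]
  out[order(out$score, out$offset), , drop = FALSE]
}

#' Calibrate a scan threshold on motif-free coverage
#'
#' Simulates flat Poisson coverage profiles containing no planted structure,
#' scans them for the motif, and returns the 1st percentile of the null
#' scores, so that at the returned threshold about one window in a hundred
#' of plain coverage would be flagged.
#'
#' @param motif Motif word (string or integers).
#' @param config An [SVWaveConfig-class].
#' @param seed Random seed.
#' @param nNull Number of null profiles.
#' @param meanCoverage Poisson mean of the null coverage.
#' @param probs Percentile of null scores (default 0.01).
#' @return The calibrated threshold.
#' @export
calibrateScanThreshold <- function(motif, config = SVWaveConfig(), seed = 1L,
                                   nNull = 200L, meanCoverage = 30,
                                   probs = 0.01) {
  len <- 2L * config@halfWidth
  scores <- withSeed(seed, {
    unlist(lapply(seq_len(nNull), function(i) {
      prof <- stats::rpois(len, meanCoverage)
      scanProfile(prof, motif, config)$score
    }))
  })
  unname(stats::quantile(scores, probs))
}

#' Scan a coverage track for stored motifs
#'
#' Tiles the track with windows of `2 * halfWidth` bp at the given stride,
#' scans every tile for every motif with [scanProfile()], and reports hits at
#' or below the threshold as BED-like 0-based half-open intervals (the
#' matched `segLen * poolWindow` bp span). Overlapping hits of the same
#' motif are collapsed to the best-scoring one. When the motif table carries
#' an `anchor` column, each hit also reports `bpEstimate`, the 1-based
#' coordinate of the breakpoint the motif places inside the matched span.
#'
#' @param x A [CoverageTrack-class] or a BCOV path.
#' @param motifs Motif table (rows with at least `sax`; optional `motifId`,
#'   `anchor`, per-row `threshold`), or a single SAX string.
#' @param config An [SVWaveConfig-class].
#' @param contig Contig to scan (required for BCOV input with several
#'   contigs; defaults to the track's own contig).
#' @param stride Tile stride in bp (default `poolWindow`).
#' @param threshold Global score cutoff; when `NA`, calibrated per motif
#'   with [calibrateScanThreshold()].
#' @return `data.frame`: `contig`, `start` (0-based), `end`, `motifId`,
#'   `score`, `offset`, `bpEstimate`.
#' @export
scanTrack <- function(x, motifs, config = SVWaveConfig(), contig = NULL,
                      stride = NULL, threshold = config@scanThreshold) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    idx <- readBcovIndex(x)
    contig <- contig %||% idx$contig[1L]
    x <- readBcov(x, contig)
  }
  if (!is(x, "CoverageTrack")) svwStop("svw_validation", "not a coverage track")
  contig <- contig %||% trackContig(x)
  if (!identical(contig, trackContig(x)))
    svwStop("svw_lookup", paste("contig not available:", contig))
  if (is.character(motifs) && is.null(dim(motifs)))
    motifs <- data.frame(motifId = "motif1", sax = motifs)
  if (!nrow(motifs)) svwStop("svw_validation", "no motifs supplied")
  if (is.null(motifs$motifId)) motifs$motifId <- paste0("motif", seq_len(nrow(motifs)))
  pw <- config@poolWindow
  win <- 2L * config@halfWidth
  stride <- as.integer(stride %||% pw)
  depths <- trackDepths(x)
  if (length(depths) < win) return(.emptyHits())
  tileStarts <- seq(1L, length(depths) - win + 1L, by = stride)
  hits <- list()
  for (mi in seq_len(nrow(motifs))) {
    sym <- .motifSymbols(motifs$sax[mi], config@alphabetSize)
    thr <- motifs$threshold[mi] %||% threshold
    if (is.na(thr))
      thr <- calibrateScanThreshold(sym, config, seed = config@seed)
    anchor <- (motifs$anchor[mi] %||% NA_real_)
    for (ts in tileStarts) {
      sc <- scanProfile(depths[ts:(ts + win - 1L)], sym, config,
                        threshold = thr)
      if (!nrow(sc)) next
      start0 <- (ts - 1L) + sc$offset * pw
      hits[[length(hits) + 1L]] <- data.frame(
        contig = contig, start = start0,
        end = start0 + config@segLen * pw,
        motifId = motifs$motifId[mi], score = sc$score, offset = sc$offset,
        bpEstimate = if (is.na(anchor)) NA_real_
                     else start0 + anchor * pw + 1)
    }
  }
  if (!length(hits)) return(.emptyHits())
  hits <- do.call(rbind, hits)
  # collapse overlapping same-motif hits to the best-scoring one
  out <- lapply(split(hits, hits$motifId), function(h) {
    gr <- GenomicRanges::GRanges(h$contig,
                                 IRanges::IRanges(h$start + 1L, h$end))
    red <- GenomicRanges::reduce(gr)
    grp <- GenomicRanges::findOverlaps(gr, red, select = "first")
    keep <- vapply(split(seq_len(nrow(h)), grp), function(ix)
      ix[which.min(h$score[ix])], integer(1))
    h[keep, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$motifId, out$start), , drop = FALSE]
}

.emptyHits <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             motifId = character(0), score = numeric(0), offset = integer(0),
             bpEstimate = numeric(0))
}

#' Write scan hits as a BED-like TSV
#'
#' @param hits Hit table from [scanTrack()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
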