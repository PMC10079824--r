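#' Average pooling of a signal
#'
#' Compresses a vector by non-overlapping arithmetic-mean windows; a trailing
#' partial window is averaged over its actual length. The default pipeline
#' pools 512 bp depth windows by 8 bp into 64-point profiles.
#'
#' @param values Numeric vector.
#' @param window Pooling window length (>= 1).
#' @return Numeric vector of length `ceiling(length(values) / window)`.
#' @examples
#' poolAverage(1:8, 8)
#' @export
poolAverage <- function(values, window) {
  stopifnot(window >= 1)
  n <- length(values)
  if (n == 0L) return(numeric(0))
  idx <- (seq_len(n) - 1L) %/% as.integer(window)
  as.numeric(rowsum(as.numeric(values), idx, reorder = TRUE) / tabulate(idx + 1L))
}

#' Pool every row of a profile matrix
#'
#' @param X Matrix, profiles in rows.
#' @param window Pooling window.
#' @return Matrix with `ceiling(ncol(X) / window)` columns.
#' @export
poolProfiles <- function(X, window) {
  groups <- split(seq_len(ncol(X)), (seq_len(ncol(X)) - 1L) %/% as.integer(window))
  out <- vapply(groups, function(ix) rowMeans(X[, ix, drop = FALSE]),
                numeric(nrow(X)))
  matrix(out, nrow = nrow(X), dimnames = list(rownames(X), NULL))
}

#' Z-normalize a profile
#'
#' Scales to zero mean and unit variance, using the population (1/n)
#' standard deviation as is conventional before SAX discretisation. When
#' sample-level moments are supplied (mean and sd of the sequencing sample
#' the profile came from) those are used instead of the profile's own; a
#' constant profile in per-profile mode maps to all zeros.
#'
#' @param x Numeric vector.
#' @param center,scale Optional sample-level mean and standard deviation
#'   (`scale` must be > 0 when given).
#' @return Normalized numeric vector.
#' @examples
#' normalizeProfile(c(0, 2))
#' @export
normalizeProfile <- function(x, center = NULL, scale = NULL) {
  if (!is.null(scale) && (!is.null(center))) {
    if (scale <= 0) svwStop("svw_validation", "sample sd must be > 0")
    return((x - center) / scale)
  }
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - m) / s
}

#' @rdname normalizeProfile
#' @param X Matrix, profiles in rows.
#' @param stats Optional two-column matrix/data.frame of per-profile sample
#'   moments (mean, sd), one row per profile.
#' @export
normalizeProfiles <- function(X, stats = NULL) {
  if (is.null(stats))
    return(t(apply(X, 1L, normalizeProfile)))
  stats <- as.matrix(stats)
  stopifnot(nrow(stats) == nrow(X))
  t(vapply(seq_len(nrow(X)),
           function(i) normalizeProfile(X[i, ], stats[i, 1L], stats[i, 2L]),
           numeric(ncol(X))))
}

#' SAX breakpoints and distance cells
#'
#' `saxBreakpoints()` returns the `alphabetSize - 1` standard-normal
#' quantiles at `k / alphabetSize` that partition the real line into
#' equiprobable symbol cells. `saxCellTable()` returns the per-symbol
#' MINDIST cell matrix: zero for identical or adjacent symbols, otherwise the
#' gap between the inner breakpoints of the two cells.
#'
#' @param alphabetSize Alphabet size (>= 2).
#' @return `saxBreakpoints()`: numeric vector; `saxCellTable()`: symmetric
#'   `alphabetSize x alphabetSize` matrix.
#' @export
saxBreakpoints <- function(alphabetSize) {
  stopifnot(alphabetSize >= 2)
  stats::qnorm(seq_len(alphabetSize - 1L) / alphabetSize)
}

.saxCache <- new.env(parent = emptyenv())

#' @rdname saxBreakpoints
#' @export
saxCellTable <- function(alphabetSize) {
  key <- as.character(alphabetSize)
  if (!is.null(.saxCache[[key]])) return(.saxCache[[key]])
  beta <- saxBreakpoints(alphabetSize)
  a <- as.integer(alphabetSize)
  tab <- matrix(0, a, a)
  for (r in 0:(a - 1L)) for (cc in 0:(a - 1L)) {
    if (abs(r - cc) > 1L)
      tab[r + 1L, cc + 1L] <- beta[max(r, cc)] - beta[min(r, cc) + 1L]
  }
  .saxCache[[key]] <- tab
  tab
}

#' SAX transformation
#'
#' Discretises an already-normalized signal into 0-based symbols using
#' equiprobable standard-normal cells, one symbol per input point (the
#' aggregation step of classic SAX is performed beforehand by the explicit
#' average pooling, so no further piecewise aggregation happens here). A
#' value lying exactly on a cell boundary takes the upper symbol, so a
#' constant-zero signal under an even alphabet maps to symbol
#' `alphabetSize / 2`.
#'
#' @param values Normalized numeric vector (no NAs).
#' @param alphabetSize Alphabet size (>= 2).
#' @return Integer vector of symbols in `[0, alphabetSize)`.
#' @examples
#' saxTransform(c(-1, -0.1, 0.1, 1), 4)
#' @export
saxTransform <- function(values, alphabetSize) {
  if (anyNA(values)) svwStop("svw_validation", "NA/NaN in SAX input")
  findInterval(values, saxBreakpoints(alphabetSize))
}

#' SAX MINDIST distance
#'
#' The classic lower-bounding SAX distance:
#' `sqrt(originalLength / wordLength) * sqrt(sum(cell(a_i, b_i)^2))`, with
#' per-symbol cells of [saxCellTable()]. It is zero between identical or
#' adjacent-symbol words and never exceeds the Euclidean distance of the
#' normalized signals the words were derived from.
#'
#' @param a,b Equal-length 0-based symbol vectors over the same alphabet.
#' @param originalLength Length of the pre-SAX signal each word summarises
#'   (drives the compression scaling factor).
#' @param alphabetSize Alphabet size.
#' @return Non-negative distance.
#' @examples
#' saxMindist(c(0, 3), c(3, 0), originalLength = 2, alphabetSize = 4)
#' @export
saxMindist <- function(a, b, originalLength, alphabetSize) {
  if (length(a) != length(b))
    svwStop("svw_validation", "SAX words must have equal length")
  if (max(a, b) >= alphabetSize || min(a, b) < 0)
    svwStop("svw_validation", "symbol outside alphabet")
  tab <- saxCellTable(alphabetSize)
  sqrt(originalLength / length(a)) * sqrt(sum(tab[cbind(a + 1L, b + 1L)]^2))
}

#' Overlapping sliding segmentation of a SAX word
#'
#' Cuts a word into all `segLen`-symbol segments at offsets
#' `0, step, 2*step, ...` (0-based) while the segment fits. Returns a matrix
#' with one segment per row and the offsets as the `"offsets"` attribute; a
#' word shorter than `segLen` yields zero segments with a message.
#'
#' @param word Integer symbol vector.
#' @param segLen Segment length in symbols.
#' @param step Stride (>= 1).
#' @return Integer matrix (`n_segments x segLen`) with attribute `offsets`.
#' @examples
#' nrow(segmentSliding(rep(0L, 64), 32))   # 33 segments
#' @export
segmentSliding <- function(word, segLen, step = 1L) {
  stopifnot(step >= 1)
  L <- length(word)
  if (segLen > L) {
    message("segment length ", segLen, " exceeds word length ", L,
            "; no segments")
    out <- matrix(integer(0), nrow = 0, ncol = segLen)
    attr(out, "offsets") <- integer(0)
    return(out)
  }
  offsets <- seq.int(0L, L - as.integer(segLen), by = as.integer(step))
  out <- t(vapply(offsets, function(o) word[(o + 1L):(o + segLen)],
                  integer(segLen)))
  out <- matrix(out, ncol = segLen)
  attr(out, "offsets") <- offsets
  out
}

#' Dynamic time warping distance
#'
#' Square root of the minimal cumulative squared pointwise cost over monotone
#' warping paths anchored at both ends (symmetric step pattern). An optional
#' Sakoe-Chiba band constrains `|i - j|`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param band Sakoe-Chiba band half-width; `NULL`/`NA` = unconstrained.
#' @return Non-negative distance; zero iff the series are equal up to
#'   repetition of points along the warping path.
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 2, 3))
#' @export
dtwDistance <- function(x, y, band = NULL) {
  if (!length(x) || !length(y)) svwStop("svw_validation", "empty input to DTW")
  band <- band %||% -1L
  cpp_dtw(as.numeric(x), as.numeric(y), as.integer(band))
}
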