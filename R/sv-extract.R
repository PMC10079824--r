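#' Read structural-variant records from a VCF
#'
#' Parses a VCF 4.2 with symbolic SV records into a variant table plus
#' per-sample genotype (and, when present, per-sample `FT` filter) matrices.
#' Recognised `SVTYPE`s are `DEL`, `DUP`, `INS`, `INV`, `CNV_GAIN` and
#' `CNV_LOSS`; records with a missing `SVTYPE` are skipped with a warning.
#' Variant length is defined as `end - start + 1` (`INS` has `end == start`).
#'
#' @param path VCF file.
#' @return List with `variants` (`data.frame`: `variantId`, `contig`,
#'   `start`, `end`, `svtype`, `filter`, `length`), `gt` (variant x sample
#'   character matrix) and `ft` (same shape, or `NULL` when the VCF carries
#'   no `FT` format field).
#' @export
readSvVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  svtype <- as.character(info$SVTYPE)
  end <- suppressWarnings(as.integer(info$END))
  start <- GenomicRanges::start(rr)
  missing <- is.na(svtype) | !nzchar(svtype)
  if (any(missing)) {
    warning(sum(missing), " record(s) lack SVTYPE and were skipped")
  }
  end[is.na(end)] <- start[is.na(end)]
  end[svtype %in% "INS"] <- start[svtype %in% "INS"]
  variants <- data.frame(
    variantId = names(rr) %||% paste0("var", seq_along(rr)),
    contig = as.character(GenomicRanges::seqnames(rr)),
    start = start, end = end, svtype = svtype,
    filter = as.character(VariantAnnotation::filt(vcf)),
    stringsAsFactors = FALSE)
  variants$length <- variants$end - variants$start + 1L
  gt <- VariantAnnotation::geno(vcf)$GT
  ft <- tryCatch(VariantAnnotation::geno(vcf)$FT, error = function(e) NULL)
  keep <- !missing
  list(variants = variants[keep, , drop = FALSE],
       gt = if (!is.null(gt)) gt[keep, , drop = FALSE] else NULL,
       ft = if (!is.null(ft)) ft[keep, , drop = FALSE] else NULL)
}

#' Classify a VCF genotype string
#'
#' `1/1` (or `1|1`) is `HOM_ALT`; `0/1`, `1/0` and phased equivalents are
#' `HET`; anything else (hom-ref, missing, multi-allelic) is `OTHER` and is
#' excluded from profile extraction.
#'
#' @param gt Character vector of GT strings.
#' @return Character vector of `HOM_ALT` / `HET` / `OTHER`.
#' @export
classifyGenotype <- function(gt) {
  out <- rep("OTHER", length(gt))
  out[gt %in% c("1/1", "1|1")] <- "HOM_ALT"
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "HET"
  out
}

#' Filter SV records
#'
#' Keeps records whose site filter is exactly `PASS` and whose length is at
#' least `minSvLen` (default 20 bp); insertions are exempt from the length
#' test because their length on the reference is undefined. The operation is
#' idempotent.
#'
#' @param variants Variant `data.frame` from [readSvVcf()].
#' @param config An [SVWaveConfig-class].
#' @return Filtered variant `data.frame`.
#' @export
filterVariants <- function(variants, config = SVWaveConfig()) {
  if (!nrow(variants)) return(variants)
  pass <- vapply(strsplit(variants$filter, ";", fixed = TRUE),
                 function(f) identical(f, "PASS"), logical(1))
  lenOk <- variants$svtype == "INS" | variants$length >= config@minSvLen
  variants[pass & lenOk, , drop = FALSE]
}

#' Derive typed breakpoint loci from filtered variants
#'
#' Breakpoint taxonomy: insertions contribute a single breakpoint (`BP`) at
#' their position; interval SVs at least as long as the window (`2 *
#' halfWidth`) contribute a left (`L`) locus at the start and a right (`R`)
#' locus at the end; shorter interval SVs of at least `minSvLen` are
#' "special" (`spSV`) and contribute one locus at the variant midpoint
#' (`floor((start + end) / 2)`), so the whole sub-window variant fits inside
#' the profile. Copy-number gain/loss classes never yield `spSV` loci.
#'
#' @param variants Filtered variant `data.frame`.
#' @param config An [SVWaveConfig-class].
#' @return A [GenomicRanges::GRanges-class] of width-1 loci with metadata
#'   columns `variantId`, `side` and `svtype`.
#' @export
deriveLoci <- function(variants, config = SVWaveConfig()) {
  windowSize <- 2L * config@halfWidth
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$svtype == "INS")
      return(data.frame(contig = v$contig, position = v$start, side = "BP",
                        variantId = v$variantId, svtype = v$svtype))
    if (v$length >= windowSize)
      return(data.frame(contig = v$contig, position = c(v$start, v$end),
                        side = c("L", "R"), variantId = v$variantId,
                        svtype = v$svtype))
    if (v$length >= config@minSvLen &&
        !v$svtype %in% c("CNV_GAIN", "CNV_LOSS"))
      return(data.frame(contig = v$contig,
                        position = (v$start + v$end) %/% 2L, side = "spSV",
                        variantId = v$variantId, svtype = v$svtype))
    NULL
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(GenomicRanges::GRanges(variantId = character(0),
                                  side = character(0), svtype = character(0)))
  GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$position, width = 1L),
                         variantId = df$variantId, side = df$side,
                         svtype = df$svtype)
}

#' Extract depth-of-coverage profiles at breakpoint loci
#'
#' One profile is extracted per (locus, carrier sample): samples whose
#' genotype for the variant classifies as `HOM_ALT` or `HET` (and, when a
#' per-sample `FT` matrix is supplied, whose `FT` equals `PASS`). Windows
#' that would extend past a contig end are dropped, as are windows whose 512
#' values are all zero (the mechanism behind left/right count imbalances in
#' real callsets). Samples without coverage are skipped with a warning.
#'
#' @param loci `GRanges` from [deriveLoci()].
#' @param coverage Named list (by sample) of either BCOV file paths or lists
#'   of [CoverageTrack-class] objects keyed by contig.
#' @param gt Variant x sample genotype matrix (raw GT strings); rownames must
#'   contain the locus `variantId`s.
#' @param config An [SVWaveConfig-class].
#' @param ft Optional variant x sample `FT` matrix.
#' @return A [DOCProfileSet-class].
#' @export
extractProfiles <- function(loci, coverage, gt, config = SVWaveConfig(),
                            ft = NULL) {
  halfWidth <- config@halfWidth
  vals <- list(); meta <- list()
  for (sample in names(coverage)) {
    cov <- coverage[[sample]]
    for (i in seq_along(loci)) {
      locus <- loci[i]
      vid <- locus$variantId
      g <- if (vid %in% rownames(gt) && sample %in% colnames(gt))
        classifyGenotype(gt[vid, sample]) else "OTHER"
      if (g == "OTHER") next
      if (!is.null(ft) && vid %in% rownames(ft) && sample %in% colnames(ft)) {
        ftv <- ft[vid, sample]
        if (!is.na(ftv) && !identical(ftv, "PASS")) next
      }
      ctg <- as.character(GenomicRanges::seqnames(locus))
      pos <- GenomicRanges::start(locus)
      win <- tryCatch({
        if (is.character(cov)) sliceWindow(cov, ctg, pos, halfWidth)
        else if (is(cov, "CoverageTrack")) sliceWindow(cov, ctg, pos, halfWidth)
        else sliceWindow(cov[[ctg]], ctg, pos, halfWidth)
      },
      svw_out_of_bounds = function(e) NULL,
      svw_lookup = function(e) NULL)
      if (is.null(win)) next
      if (all(win == 0)) next
      vals[[length(vals) + 1L]] <- win
      meta[[length(meta) + 1L]] <- data.frame(
        sample = sample, contig = ctg, position = pos,
        side = locus$side, svtype = locus$svtype, genotype = g,
        variantId = vid, stringsAsFactors = FALSE)
    }
  }
  missingCov <- setdiff(colnames(gt), names(coverage))
  if (length(missingCov))
    warning("no coverage for sample(s): ", paste(missingCov, collapse = ", "))
  if (!length(vals)) {
    return(DOCProfileSet(
      matrix(numeric(0), nrow = 2L * halfWidth, ncol = 0),
      data.frame(sample = character(0), contig = character(0),
                 position = integer(0), side = character(0),
                 svtype = character(0), genotype = character(0),
                 variantId = character(0))))
  }
  DOCProfileSet(do.call(cbind, vals), do.call(rbind, meta))
}
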