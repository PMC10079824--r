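#' Populate a relational profile store
#'
#' Builds a [ProfileStore-class] from an extracted [DOCProfileSet-class], a
#' sample metadata table and (optionally) a motif table. Variant and
#' breakpoint tables are derived from the profile metadata; inserts that
#' would break referential integrity (e.g. profiles for samples absent from
#' the metadata) are rejected.
#'
#' @param profiles A [DOCProfileSet-class].
#' @param sampleMeta `data.frame` with `sample_id`, `population`, `sex`,
#'   `mean_coverage`, `sd_coverage`, `bcov_path`.
#' @param variants Optional variant `data.frame` (from [readSvVcf()]); when
#'   omitted a minimal variant table is reconstructed from the profiles.
#' @param motifs Optional motif table from [discoverMotifs()].
#' @return A validated [ProfileStore-class].
#' @export
populateStore <- function(profiles, sampleMeta, variants = NULL, motifs = NULL) {
  info <- as.data.frame(profileInfo(profiles))
  if (is.null(variants)) {
    v <- unique(info[, c("variantId", "contig", "svtype")])
    variants <- data.frame(variant_id = v$variantId, contig = v$contig,
                           start = NA_integer_, end = NA_integer_,
                           svtype = v$svtype, length = NA_integer_)
  } else {
    variants <- data.frame(variant_id = variants$variantId,
                           contig = variants$contig, start = variants$start,
                           end = variants$end, svtype = variants$svtype,
                           length = variants$length)
  }
  bpKey <- if (nrow(info)) unique(info[, c("variantId", "side", "position", "contig")])
           else info[, c("variantId", "side", "position", "contig")]
  breakpoints <- data.frame(
    breakpoint_id = if (nrow(bpKey)) paste0("bp", seq_len(nrow(bpKey))) else character(0),
    variant_id = bpKey$variantId, side = bpKey$side,
    position = bpKey$position, contig = bpKey$contig)
  key <- paste(info$variantId, info$side, info$position)
  bkey <- paste(breakpoints$variant_id, breakpoints$side, breakpoints$position)
  profTab <- data.frame(
    profile_id = if (nrow(info)) paste0("p", seq_len(nrow(info))) else character(0),
    breakpoint_id = breakpoints$breakpoint_id[match(key, bkey)],
    sample_id = info$sample, genotype = info$genotype)
  variants <- variants[variants$variant_id %in% c(breakpoints$variant_id, variants$variant_id), , drop = FALSE]
  new("ProfileStore",
      samples = as.data.frame(sampleMeta),
      variants = variants, breakpoints = breakpoints, profiles = profTab,
      profileMatrix = profileMatrix(profiles),
      motifs = motifs %||% data.frame())
}

#' Attach a motif table to a store
#'
#' @param store A [ProfileStore-class].
#' @param motifs Motif table from [discoverMotifs()].
#' @return The updated store.
#' @export
storeSetMotifs <- function(store, motifs) {
  store@motifs <- as.data.frame(motifs)
  validObject(store)
  store
}

#' Query a profile store
#'
#' Filters stored profiles by SV class, genotype, breakpoint side and/or
#' genomic region, and returns them as a [DOCProfileSet-class] so the result
#' can be fed straight back into clustering and discovery.
#'
#' @param store A [ProfileStore-class].
#' @param svtype,genotype,side Optional filters (exact match).
#' @param region Optional region, either a [GenomicRanges::GRanges-class] or
#'   a `"contig:start-end"` string; keeps breakpoints whose position lies in
#'   the region.
#' @return A [DOCProfileSet-class] of the matching profiles.
#' @export
storeQuery <- function(store, svtype = NULL, genotype = NULL, side = NULL,
                       region = NULL) {
  pr <- store@profiles
  bp <- store@breakpoints
  j <- match(pr$breakpoint_id, bp$breakpoint_id)
  full <- data.frame(
    sample = pr$sample_id, contig = bp$contig[j], position = bp$position[j],
    side = bp$side[j],
    svtype = store@variants$svtype[match(bp$variant_id[j], store@variants$variant_id)],
    genotype = pr$genotype, variantId = bp$variant_id[j])
  keep <- rep(TRUE, nrow(full))
  if (!is.null(svtype)) keep <- keep & full$svtype %in% svtype
  if (!is.null(genotype)) keep <- keep & full$genotype %in% genotype
  if (!is.null(side)) keep <- keep & full$side %in% side
  if (!is.null(region)) {
    if (is.character(region)) region <- GenomicRanges::GRanges(region)
    loci <- GenomicRanges::GRanges(full$contig,
                                   IRanges::IRanges(full$position, width = 1L))
    keep <- keep & IRanges::overlapsAny(loci, region)
  }
  DOCProfileSet(store@profileMatrix[, keep, drop = FALSE],
                full[keep, , drop = FALSE])
}

#' Serialise / load a profile store
#'
#' The store is written as a directory of plain TSV files (`samples.tsv`,
#' `variants.tsv`, `breakpoints.tsv`, `profiles.tsv`, `profile_depth.tsv`
#' with one row of depths per profile, and `motifs.tsv` when motifs are
#' present). `readStore()` restores an identical object.
#'
#' @param store A [ProfileStore-class].
#' @param dir Directory (created if needed).
#' @return `writeStore()`: invisibly, `dir`; `readStore()`: the store.
#' @export
writeStore <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(store@samples, "samples.tsv")
  wt(store@variants, "variants.tsv")
  wt(store@breakpoints, "breakpoints.tsv")
  wt(store@profiles, "profiles.tsv")
  utils::write.table(t(store@profileMatrix), file.path(dir, "profile_depth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (nrow(store@motifs)) wt(store@motifs, "motifs.tsv")
  invisible(dir)
}

#' @rdname writeStore
#' @export
readStore <- function(dir) {
  rt <- function(f, ...) utils::read.table(file.path(dir, f), header = TRUE,
                                           sep = "\t", stringsAsFactors = FALSE, ...)
  profiles <- rt("profiles.tsv", colClasses = "character")
  depthPath <- file.path(dir, "profile_depth.tsv")
  pm <- if (file.size(depthPath) > 0)
    t(as.matrix(utils::read.table(depthPath, sep = "\t", header = FALSE)))
  else matrix(numeric(0), nrow = 0, ncol = 0)
  dimnames(pm) <- NULL
  motifPath <- file.path(dir, "motifs.tsv")
  new("ProfileStore",
      samples = rt("samples.tsv"), variants = rt("variants.tsv"),
      breakpoints = rt("breakpoints.tsv"), profiles = profiles,
      profileMatrix = pm,
      motifs = if (file.exists(motifPath)) rt("motifs.tsv") else data.frame())
}
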