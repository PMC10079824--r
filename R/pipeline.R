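.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}

#' Build workflow: coverage + VCF to profile store and motifs
#'
#' Runs the full resource-construction pipeline: read sample metadata and SV
#' VCF, filter variants (site PASS, minimum length), derive typed breakpoint
#' loci, extract depth profiles from per-sample BCOV files, populate the
#' relational store, and run bootstrap motif discovery for every
#' (svtype, side, genotype) combination with enough profiles. All outputs
#' (store directory, `motifs.tsv`/`motifs.json`, `report.json`) are written
#' under `outDir`; reruns with identical inputs, config and seed produce
#' byte-identical motif files. An empty (or fully filtered) VCF yields an
#' empty store and no motifs, with a warning. Any stage failure aborts with
#' a stage-tagged error and removes the partial output directory.
#'
#' @param vcf Path to the SV VCF.
#' @param meta Path to the sample metadata TSV (`sample_id`, `population`,
#'   `sex`, `mean_coverage`, `sd_coverage`, `bcov_path`; BCOV paths are
#'   resolved relative to the metadata file).
#' @param config An [SVWaveConfig-class].
#' @param outDir Output directory.
#' @param minPoolSize Minimum profiles required to attempt discovery for a
#'   combination.
#' @param ignoreGenotype Pool homozygous and heterozygous carriers together
#'   (label `ANY`), tripling pool sizes for rare classes.
#' @return List: `store` ([ProfileStore-class]), `motifs` (`data.frame`),
#'   `report` (list).
#' @export
runBuild <- function(vcf, meta, config = SVWaveConfig(), outDir,
                     minPoolSize = 2L * config@kClusters,
                     ignoreGenotype = FALSE) {
  created <- !dir.exists(outDir)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(outDir, recursive = TRUE))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  sampleMeta <- .stage("metadata", {
    m <- utils::read.table(meta, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("sample_id", "bcov_path")
    if (!all(need %in% colnames(m))) stop("metadata lacks sample_id/bcov_path")
    m
  })
  vcfData <- .stage("vcf", readSvVcf(vcf))
  if (!is.null(vcfData$gt)) {
    extra <- setdiff(colnames(vcfData$gt), sampleMeta$sample_id)
    if (length(extra))
      stop(sprintf("[stage vcf] samples absent from metadata: %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  filtered <- .stage("filter", filterVariants(vcfData$variants, config))
  loci <- .stage("derive", deriveLoci(filtered, config))
  coverage <- stats::setNames(
    file.path(dirname(meta), sampleMeta$bcov_path), sampleMeta$sample_id)
  profiles <- .stage("extract", {
    if (length(loci) == 0L || is.null(vcfData$gt))
      extractProfiles(loci, stats::setNames(list(), character(0)),
                      gt = matrix(character(0), 0, 0), config = config)
    else extractProfiles(loci, as.list(coverage), gt = vcfData$gt,
                         config = config, ft = vcfData$ft)
  })
  store <- .stage("populate",
                  populateStore(profiles, sampleMeta, variants = filtered))

  info <- as.data.frame(profileInfo(profiles))
  if (ignoreGenotype && nrow(info)) info$genotype <- "ANY"
  combos <- if (nrow(info))
    unique(info[, c("svtype", "side", "genotype")]) else info[0, ]
  if (nrow(combos))
    combos <- combos[order(combos$svtype, combos$side, combos$genotype), ,
                     drop = FALSE]
  motifs <- .stage("discover", {
    rows <- list()
    for (i in seq_len(nrow(combos))) {
      cb <- combos[i, ]
      sel <- info$svtype == cb$svtype & info$side == cb$side &
        (ignoreGenotype | info$genotype == cb$genotype)
      if (sum(sel) < minPoolSize) next
      X <- t(profileMatrix(profiles)[, sel, drop = FALSE])
      stats <- as.matrix(sampleMeta[match(info$sample[sel],
                                          sampleMeta$sample_id),
                                    c("mean_coverage", "sd_coverage")])
      comboSeed <- (config@seed + 7919L * i) %% .Machine$integer.max
      m <- discoverMotifs(X, config, seed = comboSeed, stats = stats,
                          labels = list(svtype = cb$svtype, side = cb$side,
                                        genotype = cb$genotype))
      m$nProfiles <- sum(sel)
      rows[[length(rows) + 1L]] <- m
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out$motifId <- sprintf("%s_%s_%s_c%d", out$svtype, out$side,
                             out$genotype, out$cluster)
      out
    } else data.frame()
  })

  if (!nrow(store@profiles))
    warning("no profiles extracted; store is empty and no motifs were built")
  store <- storeSetMotifs(store, motifs)
  writeStore(store, file.path(outDir, "store"))
  if (nrow(motifs)) writeMotifs(motifs, file.path(outDir, "motifs.tsv"))
  report <- list(
    n_variants_input = nrow(vcfData$variants),
    n_variants_pass = nrow(filtered),
    n_loci = length(loci),
    n_profiles = nrow(store@profiles),
    profiles_by_class = if (nrow(info))
      as.list(table(paste(info$svtype, info$side, sep = "/"))) else list(),
    n_motifs = nrow(motifs),
    config = .configAsList(config))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  list(store = store, motifs = motifs, report = report)
}

#' Scan workflow: BCOV + motif file to hit table
#'
#' Validates that the motif file is parameter-compatible with the config
#' (alphabet size, segment length, pooling window - an incompatibility is
#' reported naming the mismatched field), then delegates to [scanTrack()]
#' and writes the BED-like hit TSV.
#'
#' @param bcov BCOV path (or a [CoverageTrack-class]).
#' @param motifs Motif table, or the path to a `motifs.tsv` from
#'   [runBuild()].
#' @param config An [SVWaveConfig-class].
#' @param out Optional output TSV path.
#' @param contig,stride,threshold Passed to [scanTrack()].
#' @return The hit `data.frame` (invisibly written to `out` when given).
#' @export
runScan <- function(bcov, motifs, config = SVWaveConfig(), out = NULL,
                    contig = NULL, stride = NULL,
                    threshold = config@scanThreshold) {
  if (is.character(motifs) && length(motifs) == 1L) {
    if (!file.exists(motifs)) svwStop("svw_validation", "no motifs supplied")
    motifs <- readMotifs(motifs)
  }
  if (is.null(motifs) || !NROW(motifs))
    svwStop("svw_validation", "no motifs supplied")
  segBp <- nchar(motifs$sax[1L])
  if (config@alphabetSize <= 26L && segBp != config@segLen)
    svwStop("svw_config_mismatch",
            sprintf("motif parameter mismatch in field 'segLen': motif %d vs config %d",
                    segBp, config@segLen))
  hits <- scanTrack(bcov, motifs, config, contig = contig, stride = stride,
                    threshold = threshold)
  if (!is.null(out)) writeHits(hits, out)
  hits
}
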