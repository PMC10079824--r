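#' Simulation specification for a synthetic coverage sample
#'
#' Describes one synthetic whole-genome-like sample: contig length, baseline
#' mean coverage (default 30x, typical of short-read population cohorts),
#' the noise model, and a table of planted SV events. Inside an event the
#' Poisson rate is scaled by a genotype-dependent copy factor: homozygous
#' deletions (and CNV losses) x0, heterozygous x0.5; duplications and CNV
#' gains x2 (hom) / x1.5 (het); inversions keep x1 coverage but dip linearly
#' to `invDipFactor` over a `invShoulder` bp shoulder at each breakpoint (a
#' synthetic stand-in for alignment edge artifacts); insertions keep x1 with
#' a narrow dip (`insDipFactor` over +/- `insDipHalf` bp) at the insertion
#' point.
#'
#' @param contigLength Contig length in bp.
#' @param events `data.frame` with `svtype`, `start`, `length`, `genotype`
#'   (`HOM_ALT`/`HET`); events must not overlap.
#' @param contig Contig name.
#' @param meanCoverage Baseline Poisson mean.
#' @param noise `"poisson"` or `"nbinom"` (overdispersed).
#' @param dispersion Negative-binomial size when `noise = "nbinom"`.
#' @param invShoulder,invDipFactor,insDipFactor,insDipHalf Breakpoint
#'   artifact parameters (see above).
#' @return A `svwSimSpec` list.
#' @export
simSpec <- function(contigLength, events = NULL, contig = "chr1",
                    meanCoverage = 30, noise = c("poisson", "nbinom"),
                    dispersion = 10, invShoulder = 50, invDipFactor = 0.3,
                    insDipFactor = 0.5, insDipHalf = 15) {
  noise <- match.arg(noise)
  if (is.null(events))
    events <- data.frame(svtype = character(0), start = integer(0),
                         length = integer(0), genotype = character(0))
  stopifnot(all(events$length >= 1), all(events$start >= 1))
  if (nrow(events) > 1L) {
    ev <- events[order(events$start), ]
    ends <- ev$start + ev$length - 1L
    if (any(ev$start[-1] <= ends[-length(ends)]))
      svwStop("svw_validation", "events must not overlap")
  }
  if (nrow(events) && any(events$start + events$length - 1L > contigLength))
    svwStop("svw_validation", "event extends past the contig end")
  structure(list(contigLength = as.integer(contigLength), contig = contig,
                 meanCoverage = meanCoverage, noise = noise,
                 dispersion = dispersion, events = events,
                 invShoulder = invShoulder, invDipFactor = invDipFactor,
                 insDipFactor = insDipFactor, insDipHalf = insDipHalf),
            class = "svwSimSpec")
}

.copyFactor <- function(svtype, genotype) {
  hom <- genotype == "HOM_ALT"
  switch(svtype,
         DEL = , CNV_LOSS = if (hom) 0 else 0.5,
         DUP = , CNV_GAIN = if (hom) 2 else 1.5,
         1)
}

#' Simulate a coverage sample with planted SVs
#'
#' Draws per-base depth from the spec's noise model around a rate profile
#' shaped by the planted events, and emits matching PASS variant records.
#'
#' @param spec A [simSpec()] object.
#' @param seed Random seed.
#' @param sampleId Sample identifier for the variant records.
#' @return List: `track` ([CoverageTrack-class]), `variants` (`data.frame`
#'   with `variantId`, `contig`, `start`, `end`, `svtype`, `filter`,
#'   `length`, `genotype`), `stats` (`c(mean, sd)` of the track).
#' @export
simulateSample <- function(spec, seed = 1L, sampleId = "S1") {
  stopifnot(inherits(spec, "svwSimSpec"))
  len <- spec$contigLength
  rate <- rep(1, len)
  ev <- spec$events
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; L <- ev$length[i]; e <- s + L - 1L
    type <- ev$svtype[i]; gt <- ev$genotype[i]
    if (type %in% c("DEL", "CNV_LOSS", "DUP", "CNV_GAIN")) {
      rate[s:e] <- .copyFactor(type, gt)
    } else if (type == "INV") {
      sh <- min(spec$invShoulder, (L - 1L) %/% 2L)
      dip <- spec$invDipFactor
      if (gt == "HET") dip <- (1 + dip) / 2
      if (sh >= 1) {
        ramp <- seq(dip, 1, length.out = sh + 1L)
        rate[s:(s + sh)] <- pmin(rate[s:(s + sh)], ramp)
        rate[(e - sh):e] <- pmin(rate[(e - sh):e], rev(ramp))
      }
    } else if (type == "INS") {
      dip <- spec$insDipFactor
      if (gt == "HET") dip <- (1 + dip) / 2
      lo <- max(1L, s - spec$insDipHalf); hi <- min(len, s + spec$insDipHalf)
      rate[lo:hi] <- dip
    }
  }
  mu <- spec$meanCoverage * rate
  depths <- withSeed(seed, {
    if (spec$noise == "poisson") stats::rpois(len, mu)
    else stats::rnbinom(len, size = spec$dispersion, mu = mu)
  })
  depths <- pmin(depths, 65535L)
  variants <- if (nrow(ev)) data.frame(
    variantId = paste0(sampleId, "_v", seq_len(nrow(ev))),
    contig = spec$contig, start = ev$start,
    end = ifelse(ev$svtype == "INS", ev$start, ev$start + ev$length - 1L),
    svtype = ev$svtype, filter = "PASS",
    length = ifelse(ev$svtype == "INS", 1L, ev$length),
    genotype = ev$genotype)
  else data.frame()
  track <- CoverageTrack(spec$contig, depths)
  list(track = track, variants = variants,
       stats = c(mean = mean(depths), sd = stats::sd(depths)))
}

#' Write a VCF of SV records
#'
#' Minimal VCF 4.2 writer for symbolic SV records with `SVTYPE`/`END` INFO
#' and `GT`/`FT` FORMAT fields, as consumed by [readSvVcf()].
#'
#' @param variants `data.frame` with `variantId`, `contig`, `start`, `end`,
#'   `svtype` and (site) `filter`.
#' @param gt Variant x sample matrix of GT strings (rownames = variantId).
#' @param path Output path.
#' @param contigLengths Named vector for the `##contig` header lines.
#' @param ft Optional variant x sample matrix of per-sample filters.
#' @return Invisibly, `path`.
#' @export
writeSvVcf <- function(variants, gt, path, contigLengths = NULL, ft = NULL) {
  samples <- colnames(gt)
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FILTER=<ID=LowQual,Description="Low quality">',
           '##ALT=<ID=DEL,Description="Deletion">')
  if (!is.null(ft))
    hdr <- c(hdr, '##FORMAT=<ID=FT,Number=1,Type=String,Description="Per-sample filter">')
  if (!is.null(contigLengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                          as.integer(contigLengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  fmt <- if (is.null(ft)) "GT" else "GT:FT"
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    geno <- vapply(samples, function(s) {
      g <- gt[v$variantId, s]
      if (is.null(ft)) g else paste(g, ft[v$variantId, s], sep = ":")
    }, character(1))
    paste(c(v$contig, v$start, v$variantId, "N",
            paste0("<", sub("_.*", "", v$svtype), ">"), ".", v$filter,
            sprintf("SVTYPE=%s;END=%d", v$svtype, as.integer(v$end)),
            fmt, geno), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default shared variant set for cohort fixtures
#'
#' A compact mixture exercising every breakpoint class: window-sized
#' deletions, a duplication, an inversion, an insertion, sub-window "special"
#' DEL/DUP events and CNV gain/loss records.
#'
#' @param contigLength Contig length the variants must fit in.
#' @param contig Contig name.
#' @return Variant `data.frame` (`variantId`, `contig`, `start`, `end`,
#'   `svtype`, `filter`, `length`).
#' @export
cohortVariants <- function(contigLength = 60000L, contig = "chr1") {
  v <- data.frame(
    svtype = c("DEL", "DEL", "DEL", "DUP", "INV", "INS", "DEL", "DUP",
               "CNV_GAIN", "CNV_LOSS"),
    start = c(3000L, 9000L, 16000L, 22000L, 28000L, 34000L, 38000L, 41000L,
              45000L, 52000L),
    length = c(2000L, 3000L, 1200L, 2500L, 2600L, 1L, 100L, 60L, 3000L, 300L))
  stopifnot(max(v$start + v$length) < contigLength - 600L)
  data.frame(variantId = paste0("var", seq_len(nrow(v))), contig = contig,
             start = v$start,
             end = ifelse(v$svtype == "INS", v$start, v$start + v$length - 1L),
             svtype = v$svtype, filter = "PASS", length = v$length)
}

#' Write a complete synthetic cohort fixture
#'
#' Generates `nSamples` coverage samples sharing a variant set, with random
#' per-sample genotypes, and writes everything the build workflow consumes:
#' per-sample BCOV (+index) files, a multi-sample VCF with `GT`/`FT`, and a
#' sample metadata TSV.
#'
#' @param dir Output directory (created).
#' @param nSamples Number of samples.
#' @param variants Shared variant table (default [cohortVariants()]).
#' @param contigLength Contig length.
#' @param meanCoverage Baseline coverage.
#' @param seed Random seed.
#' @param genotypeProbs Probabilities of `HOM_ALT`, `HET`, hom-ref per
#'   (variant, sample).
#' @return List of paths: `vcf`, `meta`, `bcov` (named by sample), plus the
#'   `variants` and the genotype matrix `gt`.
#' @export
writeCohortFixture <- function(dir, nSamples = 4L, variants = NULL,
                               contigLength = 60000L, meanCoverage = 30,
                               seed = 1L,
                               genotypeProbs = c(0.35, 0.35, 0.30)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  variants <- variants %||% cohortVariants(contigLength)
  samples <- sprintf("S%02d", seq_len(nSamples))
  out <- withSeed(seed, {
    gtClass <- matrix(sample(c("HOM_ALT", "HET", "REF"), nSamples * nrow(variants),
                             replace = TRUE, prob = genotypeProbs),
                      nrow = nrow(variants),
                      dimnames = list(variants$variantId, samples))
    gt <- matrix("0/0", nrow(variants), nSamples,
                 dimnames = dimnames(gtClass))
    gt[gtClass == "HOM_ALT"] <- "1/1"
    gt[gtClass == "HET"] <- "0/1"
    meta <- list(); bcov <- character(0)
    for (s in samples) {
      carried <- gtClass[, s] %in% c("HOM_ALT", "HET")
      ev <- data.frame(svtype = variants$svtype[carried],
                       start = variants$start[carried],
                       length = variants$length[carried],
                       genotype = gtClass[carried, s])
      spec <- simSpec(contigLength, ev, contig = variants$contig[1L],
                      meanCoverage = meanCoverage)
      sim <- simulateSample(spec, seed = sample.int(1e6, 1L), sampleId = s)
      bcovPath <- file.path(dir, paste0(s, ".bcov"))
      writeBcov(sim$track, bcovPath)
      bcov[s] <- bcovPath
      meta[[s]] <- data.frame(sample_id = s, population = "SYN", sex = "U",
                              mean_coverage = sim$stats[["mean"]],
                              sd_coverage = sim$stats[["sd"]],
                              bcov_path = basename(bcovPath))
    }
    vcfPath <- file.path(dir, "cohort.vcf")
    cl <- stats::setNames(contigLength, variants$contig[1L])
    ft <- matrix("PASS", nrow(variants), nSamples, dimnames = dimnames(gt))
    writeSvVcf(variants, gt, vcfPath, contigLengths = cl, ft = ft)
    metaPath <- file.path(dir, "metadata.tsv")
    utils::write.table(do.call(rbind, meta), metaPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(vcf = vcfPath, meta = metaPath, bcov = bcov, variants = variants,
         gt = gt)
  })
  out
}

#' Planted-template profile pool
#'
#' Generates depth profiles that all contain the same `segLen`-point
#' template, embedded at the centre of the window (each template point spans
#' `poolWindow` bp so the template occupies the central `segLen * poolWindow`
#' bp); the flanks continue at the template's first and last values, as a
#' real breakpoint window does. Gaussian noise and optional shift/stretch
#' jitter mimic imprecise breakpoints. The default noise level, `sqrt(30)`,
#' matches the Poisson standard deviation of 30x coverage.
#'
#' @param template Numeric template of `segLen` points (coverage units).
#' @param nProfiles Number of profiles.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed Random seed.
#' @param baseline Baseline coverage outside the template.
#' @param shiftJitter Max absolute random shift of the template, bp.
#' @param stretchJitter Max relative random stretch of the template length.
#' @param halfWidth,poolWindow Window geometry (defaults match
#'   [SVWaveConfig()]).
#' @return Matrix `nProfiles x 2 * halfWidth` of non-negative depths.
#' @export
plantedMotifDataset <- function(template, nProfiles = 240L, noiseSd = sqrt(30),
                                seed = 1L, baseline = 30, shiftJitter = 0L,
                                stretchJitter = 0, halfWidth = 256L,
                                poolWindow = 8L) {
  stopifnot(nProfiles >= 1)
  len <- 2L * halfWidth
  segBp <- length(template) * poolWindow
  centerStart <- halfWidth - segBp %/% 2L   # 0-based start of the template
  withSeed(seed, {
    X <- matrix(0, nrow = nProfiles, ncol = len)
    for (i in seq_len(nProfiles)) {
      tpl <- template
      if (stretchJitter > 0) {
        f <- 1 + stats::runif(1, -stretchJitter, stretchJitter)
        m <- max(2L, round(length(template) * f))
        tpl <- stats::approx(seq_along(template), template, n = m)$y
      }
      shift <- if (shiftJitter > 0) sample(-shiftJitter:shiftJitter, 1L) else 0L
      emb <- rep(tpl, each = poolWindow)
      s <- centerStart + shift
      lo <- max(0L, s); hi <- min(len, s + length(emb))
      # flanks continue at the template's edge levels: a breakpoint window
      # does not return to a common baseline on both sides
      prof <- rep(emb[1L], len)
      if (hi < len) prof[(hi + 1L):len] <- emb[length(emb)]
      if (hi > lo) prof[(lo + 1L):hi] <- emb[(lo - s + 1L):(hi - s)]
      X[i, ] <- pmax(0, prof + stats::rnorm(len, 0, noiseSd))
    }
    X
  })
}

#' Built-in motif templates
#'
#' Idealised coverage waveforms at a breakpoint, in coverage units on a 30x
#' baseline. Transitions are ramped over `ramp` points rather than abrupt:
#' depth at real breakpoints changes over a read-length-scale shoulder
#' (imprecise breakpoint calls, soft-clipped alignments), not in a single
#' base step. `DEL_L` descends to zero at the left breakpoint of a
#' homozygous deletion, `DEL_R` ascends back, `DUP_L`/`DUP_R` shift to 2x,
#' `DEL_HET_L` descends to half coverage, and `DEL_DIP` is the full waveform
#' of a sub-window deletion (descent, zero plateau, ascent).
#'
#' @param segLen Template length in points.
#' @param baseline Baseline coverage.
#' @param ramp Transition width in points.
#' @return Named list of numeric templates.
#' @export
motifTemplates <- function(segLen = 32L, baseline = 30, ramp = 6L) {
  h <- (segLen - ramp) %/% 2L
  step <- function(from, to)
    c(rep(from, h), seq(from, to, length.out = ramp), rep(to, segLen - h - ramp))
  q <- (segLen - 2L * ramp) %/% 3L
  dip <- c(rep(baseline, q), seq(baseline, 0, length.out = ramp),
           rep(0, segLen - 2L * q - 2L * ramp),
           seq(0, baseline, length.out = ramp), rep(baseline, q))
  list(DEL_L = step(baseline, 0),
       DEL_R = step(0, baseline),
       DUP_L = step(baseline, 2 * baseline),
       DUP_R = step(2 * baseline, baseline),
       DEL_HET_L = step(baseline, baseline / 2),
       DEL_DIP = dip)
}
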