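mkVariants <- function(...) {
  df <- data.frame(...)
  df$length <- ifelse(df$svtype == "INS", 1L, df$end - df$start + 1L)
  df$variantId <- paste0("var", seq_len(nrow(df)))
  df$contig <- "chr1"
  df
}

test_that("variant filtering keeps exact-PASS records of sufficient length", {
  cfg <- SVWaveConfig()
  v <- mkVariants(start = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L),
                  end   = c(1009L, 2999L, 3019L, 4018L, 5000L, 7000L),
                  svtype = c("DEL", "DEL", "DEL", "DEL", "INS", "DUP"),
                  filter = c("PASS", "LowQual", "PASS", "PASS", "PASS",
                             "PASS;LowQual"))
  out <- filterVariants(v, cfg)
  # len-10 PASS dropped; LowQual dropped; len-20 boundary kept; len-19
  # dropped; INS exempt from the length rule; compound filter dropped
  expect_identical(out$variantId, c("var3", "var5"))
  expect_identical(filterVariants(out, cfg), out)  # idempotent
  empty <- v[0, ]
  expect_identical(nrow(filterVariants(empty, cfg)), 0L)
})

test_that("breakpoint derivation follows the side taxonomy", {
  cfg <- SVWaveConfig()
  v <- mkVariants(start = c(1000L, 10000L, 1000L, 30000L, 40000L),
                  end   = c(1000L, 19999L, 1099L, 30299L, 45000L),
                  svtype = c("INS", "DEL", "DEL", "CNV_GAIN", "CNV_LOSS"),
                  filter = "PASS")
  loci <- deriveLoci(v, cfg)
  df <- data.frame(pos = GenomicRanges::start(loci), side = loci$side,
                   vid = loci$variantId)
  expect_identical(df[df$vid == "var1", ]$side, "BP")
  expect_identical(df[df$vid == "var1", ]$pos, 1000L)
  expect_identical(df[df$vid == "var2", ]$side, c("L", "R"))
  expect_identical(df[df$vid == "var2", ]$pos, c(10000L, 19999L))
  # sub-window SV anchored at the midpoint
  expect_identical(df[df$vid == "var3", ]$side, "spSV")
  expect_identical(df[df$vid == "var3", ]$pos, 1049L)
  # CNVs never yield spSV loci; window-sized CNVs get L/R
  expect_false("var4" %in% df$vid)
  expect_identical(df[df$vid == "var5", ]$side, c("L", "R"))
  # L and R counts balance at derivation time for interval SVs
  expect_identical(sum(df$side == "L"), sum(df$side == "R"))
})

test_that("profile extraction honours genotype, bounds, FT and zero-drop", {
  cfg <- SVWaveConfig()
  v <- mkVariants(start = 5000L, end = 9999L, svtype = "DEL", filter = "PASS")
  loci <- deriveLoci(v, cfg)[1]  # L locus at 5000
  base <- CoverageTrack("chr1", rep(30L, 12000))
  zero <- CoverageTrack("chr1", rep(0L, 12000))
  gt <- matrix(c("1/1", "0/1", "0/0", "1/1"), 1,
               dimnames = list("var1", c("A", "B", "C", "D")))
  cov <- list(A = base, B = base, C = base, D = base)
  prof <- extractProfiles(loci, cov, gt, cfg)
  # one profile per carrier; hom-ref sample excluded
  expect_identical(ncol(prof), 3L)
  expect_identical(nrow(prof), 512L)
  info <- as.data.frame(profileInfo(prof))
  expect_setequal(info$sample, c("A", "B", "D"))
  expect_setequal(unique(info$genotype), c("HOM_ALT", "HET"))

  # all-zero window dropped; a sample without coverage is warned about
  expect_warning(
    prof0 <- extractProfiles(loci, list(A = zero, B = base, D = base), gt, cfg),
    "no coverage")
  expect_identical(ncol(prof0), 2L)

  # per-sample FT must be PASS when present
  ft <- matrix(c("PASS", "MinGQ", "PASS", "PASS"), 1,
               dimnames = dimnames(gt))
  expect_identical(ncol(extractProfiles(loci, cov, gt, cfg, ft = ft)), 2L)

  # off-contig window yields no profiles
  edge <- deriveLoci(mkVariants(start = 100L, end = 5000L, svtype = "DEL",
                                filter = "PASS"), cfg)[1]
  expect_identical(ncol(extractProfiles(edge, cov, gt, cfg)), 0L)
})

test_that("VCF round-trip preserves SV records, genotypes and FT", {
  v <- mkVariants(start = c(1000L, 5000L), end = c(2999L, 5000L),
                  svtype = c("DEL", "INS"), filter = c("PASS", "LowQual"))
  gt <- matrix(c("1/1", "0/1", "0/0", "1|0"), 2,
               dimnames = list(v$variantId, c("S1", "S2")))
  ft <- matrix("PASS", 2, 2, dimnames = dimnames(gt))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeSvVcf(v, gt, f, contigLengths = c(chr1 = 10000L), ft = ft)
  back <- readSvVcf(f)
  expect_identical(back$variants$start, v$start)
  expect_identical(back$variants$end, v$end)
  expect_identical(back$variants$svtype, v$svtype)
  expect_identical(back$variants$filter, v$filter)
  expect_identical(back$variants$length, c(2000L, 1L))
  expect_identical(unname(back$gt), unname(gt))
  expect_identical(unname(back$ft), unname(ft))
  expect_identical(classifyGenotype(c("1/1", "0|1", "1|0", "0/0", "./.", "2/1")),
                   c("HOM_ALT", "HET", "HET", "OTHER", "OTHER", "OTHER"))
})

test_that("the profile store enforces keys, queries and round-trips", {
  cfg <- SVWaveConfig()
  withr::with_seed(13, {
    v <- mkVariants(start = c(1000L, 5000L, 20000L),
                    end = c(1999L, 6999L, 20999L),
                    svtype = c("DEL", "DUP", "DEL"), filter = "PASS")
    tr <- CoverageTrack("chr1", rpois(30000, 30))
    gt <- matrix("1/1", 3, 2, dimnames = list(v$variantId, c("A", "B")))
    loci <- deriveLoci(v, cfg)
    prof <- extractProfiles(loci, list(A = tr, B = tr), gt, cfg)
  })
  meta <- data.frame(sample_id = c("A", "B"), population = "SYN", sex = "U",
                     mean_coverage = 30, sd_coverage = 5.5, bcov_path = "x")
  st <- populateStore(prof, meta, variants = v)
  expect_identical(nrow(st@profiles), 12L)

  del <- storeQuery(st, svtype = "DEL")
  expect_identical(ncol(del), 8L)
  expect_true(all(profileInfo(del)$svtype == "DEL"))

  reg <- storeQuery(st, region = "chr1:900-1100")
  expect_identical(unique(profileInfo(reg)$position), 1000L)

  # stored profile vectors round-trip the file serialisation exactly
  d <- withr::local_tempdir()
  writeStore(st, d)
  back <- readStore(d)
  expect_equal(back@profileMatrix, st@profileMatrix)
  expect_identical(back@profiles$breakpoint_id, st@profiles$breakpoint_id)
  q1 <- storeQuery(back, svtype = "DUP", genotype = "HOM_ALT")
  expect_identical(ncol(q1), 4L)

  # foreign-key violation: profile referencing an unknown sample
  badMeta <- meta[meta$sample_id != "B", , drop = FALSE]
  expect_error(populateStore(prof, badMeta, variants = v), "foreign-key")
})
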