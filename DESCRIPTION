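Package: SVWaveform
Title: Coverage Waveform Motif Discovery at Structural Variant Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising read-depth (depth-of-coverage) waveforms
    around structural variant breakpoints. Implements a lossless two-byte
    binary coverage format (BCOV) with an index for O(1) window slicing,
    extraction of fixed-width depth profiles at VCF-derived breakpoint loci
    (left/right breakpoints, insertion points, and sub-window "special" SVs),
    dynamic-time-warping K-means clustering of compressed profiles, SAX
    symbolic discretisation, a reference-point-pruned nearest-neighbour motif
    search over SAX segments with bootstrap aggregation into predominant
    per-class motifs, and sliding-window scanning of coverage tracks for the
    discovered motifs. A synthetic-coverage simulator with planted
    deletion/duplication/inversion/insertion events supports end-to-end
    validation without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    withr,
    jsonlite,
    cluster,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: StructuralVariation, Coverage, Clustering
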