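Package: enhancerStates
Title: Chromatin-State Classification of Putative Enhancers from Histone-Mark ChIP-seq Peaks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative enhancer elements from multi-sample H3K4me1,
    H3K27ac and H3K27me3 ChIP-seq peak sets, classifies them into five
    chromatin states (active, bivalent, H3K4me1-only, H3K27ac-only,
    H3K27me3-only) via a fractional-overlap peak consensus and a
    region-by-sample presence matrix, and characterises each state by
    genomic-location annotation, nearest-TSS distance, conservation,
    factor-occupancy hypergeometric enrichment, and cross-tissue state
    dynamics. Includes a synthetic peak-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, ChIPSeq, FunctionalGenomics, PeakDetection
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'annotate.R'
    'classify.R'
    'dynamics.R'
    'enhancerStates-package.R'
    'enrichment.R'
    'intervals.R'
    'io.R'
    'pipeline.R'
    'simulate.R'
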