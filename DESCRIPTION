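Package: clonepulse
Title: Clone Tracking and Resistance Classification from Cellular
    Barcoding Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for lentiviral cellular-barcoding
    experiments that track clonal dynamics of drug-treated 3D spheroid
    cultures. Extracts 48-nt barcodes from paired-end amplicon reads by
    fixed-position trimming, counts them against a reference barcode
    library in both orientations, computes per-clone growth rates from
    frequency ratios between treated replicates and a vehicle (DMSO)
    control, and classifies each barcode as pre-existing, de novo, or
    drug-sensitive. Also implements the companion whole-exome
    post-filters (coverage gating, two-fold variant-allele-frequency
    enrichment with control exclusion, multi-replicate copy-number
    consensus), normalized log-inhibitor dose-response IC50 fitting, and
    2^-ddCt expression fold changes. A synthetic-data generator emulates
    the experimental design (initial barcoded population, DMSO control,
    three treated replicates) with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
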