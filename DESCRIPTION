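Package: spliceRUNJ
Title: RNA-seq Validation of Predicted Splice-Altering Somatic Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates predicted splice-altering somatic mutations against
    matched tumor RNA-seq data. Parses SpliceAI-style delta-score annotations
    from VCF, selects the strongest predicted event per variant, classifies
    split and spanning reads at the affected exon-intron boundary as normal or
    abnormal, and computes the Relative Usage of the Novel Junction (RUNJ)
    statistic against panel-of-normal and panel-of-tumor controls, applying
    fixed read-support and RUNJ thresholds to call a prediction validated.
    Also maps splice events to positions relative to essential splice sites,
    reclassifies variant consequences, attributes mutations to SBS-96
    mutational signatures given per-sample exposures, and tests signatures for
    enrichment in splice versus other mutations. Includes a seeded simulator
    producing toy gene models, spliced/retained/cryptic-junction reads with
    per-read truth labels, annotated VCFs and signature-sampled mutation sets.
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
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
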