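Package: svintegrate
Title: Integration, Annotation and Visualization of Multi-Caller
    Structural Variant Predictions
Version: 0.1.0
Authors@R:
    person("Maintainer", "svintegrate", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parses the native output of seven structural-variant (SV)
    callers (BreakDancer, Pindel, CNVnator, DELLY, SVseq2, Lumpy,
    SoftSearch), applies per-caller quality filters, merges concordant
    predictions across callers by reciprocal-overlap clustering,
    annotates merged SVs against GFF3 gene models, and visualizes SV
    distributions genome-wide or per region. Includes a synthetic SV
    benchmark simulator that emits ground-truth call sets in every
    supported caller dialect, plus precision/recall evaluation against
    the planted truth, and a command-line interface covering the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    ggplot2,
    withr,
    stats,
    utils,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
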