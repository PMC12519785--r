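Package: restim
Title: Memory-Like Responses to Repeated Cytokine Stimulation in Transcriptome and Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of two-hit cytokine restimulation experiments in which cells
    (for example endothelial cells stimulated with TNF-alpha or IFN-gamma) receive a
    first stimulation, rest, and are then restimulated, with paired controls. Provides
    a paired negative-binomial generalized linear model over a five-contrast suite
    (single hit, repeated hit, rested baseline, direct restimulation and the
    baseline-controlled interaction), trajectory-based classification of genes into
    innate-immune-memory-like classes (trained, primed, tolerized, persistent),
    consensus chromatin-accessibility peak construction with shared-versus-dynamic
    categorization and TSS-window gene mapping, and a matched-background permutation
    test for disease-SNP enrichment in differential regions. A seeded synthetic-data
    module generates count matrices, peak calls and SNP catalogs with planted truth
    so every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust,
    optparse
Config/testthat/edition: 3
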