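Package: tasqc
Title: Quality Control and Adaptive Variant Calling for Targeted Amplicon
    Sequencing of FFPE Tumor DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis toolkit for deep targeted amplicon
    sequencing (TAS) of low-quality tumor DNA, such as DNA extracted from
    formalin-fixed paraffin-embedded (FFPE) tissue. Implements discovery of
    panel-specific systematic variants by testing cohort allele-fraction
    dispersion against a simulated Hardy-Weinberg mean-SD envelope;
    sample-adaptive two-dimensional variant-score thresholding that sets
    separate cutoffs for GC>AT transitions (the dominant FFPE deamination
    artifact) and all other substitutions under SNP-rediscovery constraints;
    orthogonal-platform variant confirmation with joint-threshold f-measure
    optimization and exact (Clopper-Pearson) binomial confidence intervals;
    reference DNA mixture design with linearity analytics (Lin's concordance
    correlation coefficient, expected allele-fraction CDFs, precision
    summaries); and qPCR-based pre-analytical sample qualification via the
    quantitative functional index (QFI). A seeded synthetic-data module
    generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomeInfoDb,
    jsonlite,
    methods,
    rlang,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
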