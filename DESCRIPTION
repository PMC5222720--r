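Package: XCIquant
Title: Scoring X-Chromosome Activity from Allele-Specific Single-Cell
    RNA-Seq and RNA-FISH Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for studying the onset of X-chromosome
    inactivation in early human embryos and naive pluripotent stem cells.
    Implements a coverage-normalized bi-allelic-position statistic for
    per-cell X-chromosome activity from allele-specific single-cell
    RNA-seq counts, an empirical gene-null for XIST co-expression
    analysis, and 3D RNA-FISH image metrics (computed intensity
    thresholds, cloud segmentation, volume, dispersion, per-nucleus
    co-localization, and allelic-pattern contingency tests), together
    with seed-deterministic synthetic-data generators with full ground
    truth for both the sequencing and imaging arms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Epigenetics, CellBiology, Software
RoxygenNote: 7.3.3
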