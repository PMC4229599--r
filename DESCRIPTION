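Package: robustmatch
Title: Transcriptome-Phenotype Matching for Fermentation-Induced Stress Robustness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping bacterial stress-robustness phenotypes onto
    transcriptome profiles across combinatorially designed fermentations.
    Covers stress-survival scoring from colony counts (log10 CFU reduction),
    maximum-specific-growth-rate estimation from OD curves, two-color
    microarray preprocessing (MA transform, lowess dye-bias normalization,
    per-array scaling, median probe-to-ORF summarization), per-parameter
    differential-expression overlap matrices, selection of robustness
    "transcriptome signatures" by a dual-time-point p-value-product
    criterion, detection of genetically linked gene groups from intergenic
    spacing, and a seeded synthetic-data generator that reproduces the
    statistical structure of such experiments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
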