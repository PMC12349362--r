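Package: rugosity
Title: Quantification of Fruit Surface Rugosity and Associated Texture and
    Expression Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies epidermal surface rugosity of fruit cross-sections
    via a contour-based rugosity index (percent excess of the traced
    epidermal arc length over the section length), classifies fruits into
    four ordinal rugosity levels, and runs the associated statistics:
    sensory-grade validation regression, per-level one-way ANOVA with Tukey
    HSD compact letter displays, pairwise t-tests, Pearson correlation
    matrices, and level-ratio summaries. Also provides operationally defined
    transcriptome computations (FPKM, fold-change/FDR differential-expression
    filtering, standardized K-means co-expression modules, sample PCA, and
    2^-ddCt relative qPCR quantification) plus synthetic-data generators with
    known ground truth for contours, calibrated section images, phenotype
    populations, count matrices and Ct tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    DESeq2,
    mclust,
    pracma
Config/testthat/edition: 3
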