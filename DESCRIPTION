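Package: aggscreen
Title: Sorted-Bin CRISPRi Screen and Lipidomic Association Analysis for
    Protein Aggregation Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of FACS sorted-bin CRISPRi screens
    that read out endogenous protein aggregation with an amyloid-binding
    dye. Provides a generative model of a quartile-sorted screen with a
    cell-size covariate, median-of-ratios count normalization, gene-level
    log2 fold changes with a non-targeting-guide permutation null and
    Benjamini-Hochberg FDR, a volcano-product hit rule, a signed prerank
    score combining effect size and confidence, preranked gene-set
    enrichment analysis, per-lipid-species regression against the
    aggregation phenotype with lipid-class Kolmogorov-Smirnov enrichment,
    and ratiometric flow-cytometry quantification (spike-in double
    normalization, lysosomal pH reporter ratios, and galectin-3 puncta
    scoring of lysosomal membrane permeabilization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    DESeq2
Config/testthat/edition: 3
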