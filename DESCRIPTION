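Package: methylGOF
Title: Goodness-of-Fit Non-Specific Filters for Beta-Distributed DNA
    Methylation Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-specific (label-blind) feature filters for DNA methylation
    proportions modelled by Beta distributions, including goodness-of-fit
    filters built on the cumulative-distribution-function variance-stabilizing
    transform (TM-GOF, TQ-GOF, BQ-GOF), classical variability filters (SD on
    beta or M-values, MAD, dip statistic, inverse precision) and rank
    combinations (best rank, average rank, weighted average rank). Includes a
    two-group Beta-mixture simulator of CpG island methylator phenotype style
    data sets, a recursive two-component Beta-mixture partitioning of samples,
    and ROC / misclassification / adjusted Rand evaluation of filter
    performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    tools,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    pROC,
    jsonlite,
    optparse
biocViews: DNAMethylation, Clustering, Epigenetics, FeatureExtraction,
    StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
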