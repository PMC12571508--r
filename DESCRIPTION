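Package: hiertox
Title: Hierarchical Linear Model Tests and Pathway Mining for Toxicogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential expression testing for nested toxicogenomics designs
    (compound group, compound, dose, time point, replicate) with a hierarchical
    linear model F-statistic computed through quadratic forms, intracluster
    correlation estimation, and a leave-(b-1)-out refinement that removes
    chemical-specific outlier genes. Includes a synthetic-data generator with
    nested random intercepts for power and type-I error studies, pooled Welch
    and moderated-t comparator tests, association-rule mining of gene-disease
    adverse-outcome links over compound transactions, hypergeometric
    over-representation analysis against GMT gene-set databases, protein-protein
    interaction community detection with core-gene selection, and gene-signature
    evaluation by cross-validated logistic regression, Ward clustering, and a
    random-signature cross-correlation null.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    cluster,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), limma, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
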