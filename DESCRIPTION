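Package: uniD
Title: Unified DNA Methylation-Based Molecular Diagnostics for Infiltrating Glioma
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A unified diagnostic pipeline that predicts somatic genomic
    alterations and gene-expression subtypes of infiltrating gliomas from
    Infinium DNA-methylation beta-value matrices. Implements probe- and
    sample-level quality control for HM27K/HM450K/EPIC arrays (static probe
    filters, detection-p and beadcount masking, missingness thresholds,
    k-nearest-neighbour imputation), elastic-net stability selection with
    selection-percentage probe ranking, penalized logistic models for IDH,
    TERT promoter and ATRX mutation and chr1p/19q co-deletion status, an
    entropy-metric ranked random-forest classifier for the classical,
    proneural and mesenchymal expression subtypes, signature enrichment
    analytics, a consensus-NMF admixture harness for evaluating cross-platform
    batch adjustment, and seeded synthetic cohort generators for end-to-end
    testing without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    jsonlite,
    yaml,
    MASS,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
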