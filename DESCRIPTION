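Package: fedgeno
Title: Federated Learning on Distributed Genomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-node genotype, phenotype and ancestry cohorts with a
    controllable population-structure dial, runs per-node quality control,
    genome-wide association with random-effects meta-analysis, exact federated
    principal component analysis by eigenvector stacking, and trains polygenic
    LASSO banks and ancestry classifiers with federated averaging (FedAvg),
    comparing local, federated and centralized models under a common
    cross-validation harness with communication accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    cluster
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    metafor,
    withr
Config/testthat/edition: 3
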