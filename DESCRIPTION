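Package: cdmli
Title: Mucosal-Luminal Interface Microbiome Analysis for Crohn's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for colonic mucosal-luminal interface (MLI)
    microbiome cohorts contrasting Crohn's disease in endoscopic remission
    with non-IBD controls. Provides a synthetic-cohort generator with known
    ground truth (paired cecum/sigmoid negative-binomial counts, biallelic
    genotypes with log-odds weights, log-normal LC-MS intensities with
    intensity-dependent missingness), alpha/beta diversity with
    covariate-adjusted PERMANOVA, negative-binomial differential abundance
    with dispersion shrinkage, the CD dysbiosis index, polygenic genetic
    risk scores and their microbiome associations, a two-stage random-forest
    biomarker classifier with bootstrap AUC intervals, and an untargeted
    metabolomics stage culminating in the cholate:deoxycholate log ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
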