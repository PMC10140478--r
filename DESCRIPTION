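Package: twinbile
Title: Twin-Cohort Heritability and Microbiome Prediction of Metabolite Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for serum and stool metabolite phenotypes
    (bile acids in particular) measured in twin cohorts. Provides metabolite
    quality control and normalisation (missingness filtering, per-batch median
    scaling, minimum-value imputation, rank-based inverse normal transform),
    maximum-likelihood ACE twin variance decomposition with AIC model selection
    and profile-likelihood confidence intervals, twin-aware cross-validated
    random-forest prediction of metabolites from gut-microbiome relative
    abundances, covariate-adjusted partial Spearman screens with
    Benjamini-Hochberg control, two-cohort concordance gating, post-prandial
    peak/delta linear models, DerSimonian-Laird random-effects meta-analysis,
    paired t-tests for intervention change, and complete-linkage clustering.
    A synthetic-data generator with known ground truth makes every stage
    testable end to end without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC,
    metafor,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
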