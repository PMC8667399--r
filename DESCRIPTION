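Package: loyprs
Title: Polygenic Risk Prediction of Mosaic Loss of Chromosome Y
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for predicting mosaic loss of
    chromosome Y (LOY) in blood from a polygenic risk score (PRS). Implements
    LOY calling from array intensity data via the median Log R Ratio over
    male-specific chromosome Y probes (mLRRY), an empirical-null calling
    threshold, conversion of mLRRY to the percentage of affected cells, PRS
    construction from GWAS weights with variant quality control and allele
    alignment, quintile risk-group stratification, association and prediction
    modelling (logistic and linear regression, ANCOVA, ROC/AUC with DeLong's
    test for correlated curves), and concordance of array-derived LOY with
    whole-genome-sequencing read-depth estimates. A seeded synthetic-cohort
    generator with known ground truth makes every stage testable without
    access to controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
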