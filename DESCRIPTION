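Package: omega3grs
Title: Genetic Risk Scores for the Plasma Triglyceride Response to
    Omega-3 Fatty Acid Supplementation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and evaluates genetic risk scores (GRS) that predict
    whether an individual's plasma triglyceride level falls after a fish-oil
    (omega-3 fatty acid) supplementation. Provides genotype input from PLINK
    text or VCF, per-variant quality control (minor-allele frequency,
    Hardy-Weinberg exact test, monomorphism), allele-based odds ratios
    between responders and nonresponders with the +1/-1 score-assignment
    rule, unweighted and weighted GRS summation over nested score panels,
    covariate-adjusted logistic and linear prediction models with McFadden
    pseudo R-squared and explained-variance contributions, stratified
    split/cross-validation discrimination metrics (accuracy, AUC-ROC,
    sensitivity, specificity), GRS cutoff sweeps with a decision-aid rule,
    and a synthetic-cohort generator emulating the responder/nonresponder
    structure of an intervention study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    withr
Config/testthat/edition: 3
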