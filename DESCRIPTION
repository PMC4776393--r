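Package: embryoselect
Title: Embryo Implantation Prediction from Computer-Assisted Morphometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives computer-assisted (CASS) morphometric features (total
    cytoplasmic volume, coefficient of diversity, volume-loss fragmentation)
    from blastomere diameter measurements of cleavage-stage embryos, builds
    clinical-pregnancy prediction models by maximum-likelihood logistic
    regression with two-way interactions and backward stepwise elimination and
    by multivariate adaptive regression splines (MARS) with GCV pruning and
    10-fold cross-validation, evaluates them with ROC/AUC, DeLong comparison
    tests and agreement statistics (ICC, Cohen's kappa), ranks embryos per
    patient, and ships a synthetic cohort generator with volume-conserving
    embryo geometry and a known outcome model so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
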