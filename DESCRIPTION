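Package: ternmeth
Title: Ternary Smoking-Status Classification from Blood DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to build and evaluate ternary (current/former/never)
    smoking-status classifiers from DNA-methylation beta values. Implements
    weighted CpG classification scores, ROC construction with the
    closest-to-(0,1) optimal-threshold rule, DeLong variance and paired
    AUC comparison, a two-stage binary-then-ternary classifier with frozen
    thresholds, a confusion-matrix evaluation battery (accuracy with exact
    binomial confidence intervals, no-information rate, unweighted kappa,
    per-class sensitivity/specificity/PPV/NPV), Riley-criteria bounds on
    the number of score parameters, cross-validated LASSO score derivation,
    and a logit-normal synthetic methylation generator with persistent,
    reverting and partially-reverting CpG classes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    caret,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
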