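Package: scalesdm
Title: Multi-Scale Ensemble Species Distribution Modeling with Scenario
    Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multi-scale ensemble species distribution models from
    presence-only occurrences: moving-window focal predictors at candidate
    radii, characteristic-scale selection by presence-background t-tests,
    correlation screening, an AUC-weighted ensemble of five algorithms
    evaluated by repeated cross-validation (AUC, TSS, continuous Boyce
    index), maxSSS binarization, scenario projection with climate-model
    averaging and dispersal constraints, habitat gain/loss/turnover
    accounting, time-step maps, and minimum-convex-polygon range
    diagnostics. Includes a seeded synthetic-landscape generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    mgcv,
    glmnet,
    ranger,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
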