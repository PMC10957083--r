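Package: raytox
Title: Concentration-Response Fitting and Binary Mixture Toxicity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for acute aquatic toxicity bioassays with single toxicants
    and binary mixtures. Fits sigmoidal concentration-response curves (Weibull,
    Box-Cox-Weibull and generalised logit families) by multi-start nonlinear
    least squares, estimates lethal concentrations (LCx) with observation
    confidence bands, designs fixed-ratio binary mixture experiments by the
    equi-effect concentration ratio (EECR) and direct equipartition ray
    (EquRay) methods, predicts mixture toxicity under concentration addition
    (Loewe) and independent action models or a composition-based regression
    surrogate, and classifies component interactions by synergistic ratio.
    Includes a seeded binomial-mortality simulator for power and recovery
    studies, GHS acute hazard classing, and an end-to-end pipeline producing
    report tables from flat mortality records.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    glmnet,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
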