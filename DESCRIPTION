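Package: stressorcurves
Title: Gradient-Based Analysis of Multiple-Stressor Interactions on
    Performance Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how multiple environmental stressors
    interact along continuous gradients. Extracts microbial population
    growth rates from plate-reader optical density time series by fitting
    the Gompertz growth model, characterises environmental performance
    curves with quadratic mixed-effects models on orthogonal polynomials
    selected by AICc, computes additive and multiplicative null-model
    predictions of combined-stressor growth at every gradient level,
    quantifies deviations from the null with bias-corrected Hedge's d and
    classifies interactions as additive, antagonistic or synergistic, and
    models how interaction effect sizes change along gradients with
    penalized cubic regression spline GAMs. Includes a synthetic plate
    data generator with known ground truth for validation, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    mgcv,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
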