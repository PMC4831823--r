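Package: inhibinorm
Title: Age-Specific Normative Modelling of Serum Inhibin B in Boys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction of an age-specific normative model of serum
    inhibin B in males from birth to 17 years. Fits boundary-anchored
    rational-polynomial (Pade-form) mean curves to square-root transformed
    hormone levels by two-stage least squares, justifies the square-root
    scale by Box-Cox profile likelihood, enumerates and selects candidate
    degrees under non-negativity and parsimony rules, estimates prediction
    error by k-fold cross-validation and bootstrap resampling, and turns
    the fitted curve into centile tables, confidence bands and prediction
    bands. Includes a synthetic cohort generator emulating the age mixture
    of the combined published studies, so the full pipeline is testable
    without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
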