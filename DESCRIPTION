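Package: hsmax
Title: Presence-Only Habitat Suitability Modelling with Maximum Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for presence-only habitat suitability
    modelling of sessile species at protected-area scale. Implements a
    presence-background maximum-entropy model (linear, quadratic, product,
    hinge and threshold features with L1-style regularization, cloglog
    output), a five-step environmental-variable selection workflow
    (permutation-importance ranking, percent-contribution screening,
    Pearson pair filtering, variance-inflation-factor elimination, top-k
    selection), regularization-multiplier by feature-class tuning with
    sample-size-corrected AIC, bootstrap replicate evaluation (AUC,
    AUC difference, 10 percent omission rate), maximum test sensitivity
    plus specificity thresholding with equal-interval suitability
    classification, and species range-change accounting (loss, stable,
    gain, SRC) between current and future climate scenario stacks.
    Ships a synthetic-landscape generator (spatially autocorrelated
    environmental layers, known true suitability surfaces, occurrence
    sampling, future-scenario perturbation) so the whole workflow is
    testable without external data, plus ESRI ASCII grid input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
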