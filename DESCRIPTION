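Package: neuronorm
Title: Warped Bayesian Normative Models of Regional Brain Measures Across the Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative ("reference cohort") modelling of region-of-interest brain
    measures such as cortical thickness and subcortical volume over the human
    lifespan. Fits, per region, a Bayesian linear regression on sinh-arcsinh
    (SHASH) warped responses with a cubic B-spline age basis, a sex offset and
    fixed site effects, optimising hyperparameters by type-II maximum
    likelihood. Provides deviation Z-scores, centile charts, explained-variance
    and standardized log-loss evaluation, transfer of trained models to unseen
    scan sites via latent-space recalibration, automated quality control from
    the Freesurfer Euler characteristic, and transdiagnostic clinical
    summaries (extreme-deviation maps and FDR-controlled case-control tests).
    Includes a multi-site synthetic cohort generator with known ground truth so
    the whole pipeline is testable without access to restricted neuroimaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    splines,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
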