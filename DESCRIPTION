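Package: snowmotility
Title: Thermal Motility Analysis of Snow-Algal Microswimmers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis chain for temperature-dependent motility
    of ciliated microalgae. Generates synthetic microswimmer recordings,
    detects spots by difference-of-Gaussians filtering, links them into
    tracks with a linear-assignment-problem (LAP) tracker with gap closing,
    computes per-track motility metrics (speed, confinement ratio,
    dispersal) and motile/non-motile classification against a
    deciliated-control-calibrated distance threshold, fits thermal
    performance curves (Sharpe-Schoolfield/Pawar, Thomas2, Weibull) by
    weighted nonlinear regression with residual-resampling bootstrap
    confidence intervals and AIC model selection, scores Petri-dish
    phototaxis assays, and reports cross-species trait correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
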