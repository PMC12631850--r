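Package: latstruct
Title: Latency Structure Analysis of Resting-State BOLD Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the lag (latency) structure of parcellated resting-state
    BOLD time series: pairwise lagged cross-covariance with sub-sample
    interpolation, thresholded antisymmetric time-delay matrices, and their
    principal-component summaries (latency eigenvectors) with Procrustes
    alignment across individuals and datasets. Includes a biophysical
    excitatory/inhibitory neural-mass simulator with feedback inhibition
    control and a Balloon-Windkessel hemodynamic forward model, intrinsic
    neural timescale estimation by offset-exponential autocorrelation fits,
    functional-connectivity gradients via cosine-affinity diffusion-map
    embedding, and permutation-based inference (spherical spin tests,
    Hotelling T-squared group comparison, cross-validated regression).
    Ships synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
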