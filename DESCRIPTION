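Package: multiddm
Title: Multiple-Alternative Drift-Diffusion Models of Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for perceptual decision making with an
    arbitrary number of alternatives. Provides the orthogonal competition basis that
    reduces winner-take-all firing-rate networks with global inhibition to
    (n-1)-dimensional drift-diffusion models, Euler-Maruyama simulators for the
    linear and nonlinear rate networks and their reduced models, the Bayesian
    multiple sequential probability ratio test and its exact moving-threshold
    drift-diffusion equivalent, quadratic/cubic stochastic normal forms with their
    analytic potential landscape, and experiment harnesses for Hick's law,
    fixed- versus moving-threshold comparisons, and network-tracking checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
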