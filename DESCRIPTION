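Package: hemoclot
Title: Continuum Thrombosis Simulation in Two-Dimensional Channel Flows
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator of device-related thrombosis. Couples
    incompressible hemodynamics with a porous-thrombus momentum sink to a
    ten-species convection-diffusion-reaction network describing platelet
    activation by biochemical agonists (ADP, thromboxane A2, thrombin) and
    shear, surface deposition with monolayer saturation, thrombus
    propagation, shear-driven cleaning, stabilization, and
    heparin-catalyzed antithrombin inhibition of thrombin.  Provides
    structured-grid surrogate geometries (straight channel,
    backward-facing step, crevice channel), a deterministic coupled
    time-stepping driver with reaction-rate time scaling, scenario
    presets (flow-rate sweep, heparin bolus, surface-coating change), and
    post-processing metrics for thrombus burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
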