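Package: rvfsim
Title: Multiscale Simulation of Right Ventricular Pressure Overload and Failure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A multiscale model of the rodent cardiovascular system coupling a
    reduced cross-bridge myofilament model (calcium-driven active force with an
    explicit maximum-force scale, titin and collagen passive stress, viscous and
    series elements) to a three-wall-segment biventricular heart and a
    closed-loop lumped-parameter circulation with time-varying atrial
    compliance. Implements scenario perturbations for bleomycin-type pulmonary
    hypertension (increased pulmonary vascular resistance, decreased pulmonary
    artery compliance, right ventricular hypertrophy, fibrosis, reduced maximum
    myocyte force), a beat-wise convergence protocol with systolic-pressure
    homeostasis, pressure-volume metrics (RVSP, EF, CO, arterial and
    end-systolic elastance, ventricular-vascular coupling, chamber compliance),
    and an in-silico treatment arm restoring myocyte force generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
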