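Package: ferridyn
Title: Ferritin Dynamics and Iron-Chelation Treatment Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Drug-disease modelling of transfusional iron overload in
    beta-thalassaemia major. Implements a serum-ferritin turnover model with
    transfusion-driven production and a proportional deferoxamine effect on
    ferritin elimination, driven by average steady-state drug exposure from a
    two-compartment infusion pharmacokinetic model with allometric scaling.
    Provides dosing-calendar and adherence-pattern generators (random missed
    doses and drug holidays), decision-support simulations of the time to
    reach the 2500 ug/L ferritin threshold, nonlinear mixed-effects
    estimation of the drug model by Laplace approximation (with bootstrap and
    visual predictive checks), and a synthetic cohort generator emulating the
    study design.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
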