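Package: bakesim
Title: Coupled Heat and Moisture Transfer Simulation of Toast-Bread Baking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates crust temperature and weight loss of toast bread
    (control and 1% guar-gum formulations) during baking by solving the
    coupled one-dimensional radial heat and moisture balances in an
    infinite cylinder, with a convective-radiative surface boundary, a
    Chilton-Colburn mass-transfer boundary, and an apparent-heat-capacity
    treatment of the evaporation front. Includes the thermophysical
    property submodels, reduction of mixing-calorimetry and transient
    hot-wire measurements to specific heat and thermal conductivity,
    quadratic predicted-versus-experimental validation regressions, and a
    synthetic-data generator that reproduces the study design (five oven
    temperatures, eight sampling times, two formulations, three
    replicates) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
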