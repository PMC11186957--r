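Package: voltaxis
Title: Excitation-Adaptation Modelling and Optimal Control of Collective
    Electrotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the bulk velocity of an epithelial monolayer steered by a
    uniaxial direct-current electric field with a three-variable linear
    excitation-adaptation system (effective signal, inhibitor, velocity),
    calibrates the kinetic parameters from bulk-velocity time series by
    least-squares decay fitting and adaptive-covariance Markov chain Monte
    Carlo, and designs stimulation protocols by optimal control: isoperimetric
    maximum-distance and maximum-terminal-velocity problems solved through
    Pontryagin adjoints in closed form, constant-velocity (cruise) and
    windowed-cruise problems solved by direct convex transcription of the
    tracking functional, and a bang-bang policy from the switching function.
    Includes a synthetic bulk-velocity trace generator emulating
    10-minute-cadence particle image velocimetry averages, file dialects for
    traces, protocols and control solutions, and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
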