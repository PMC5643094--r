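Package: oocytemt
Title: Microtubule and mRNP Track Analytics and Transport Simulation in the
    Drosophila Oocyte
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of EB1 plus-end comet tracks and oskar
    mRNP particle tracks in the stage 9 Drosophila oocyte, together with
    stochastic simulators of microtubule organisation and kinesin cargo
    transport.  Provides the oocyte cross-section geometry model
    (distances to the posterior pole and cortex, distance bands), a
    synthetic track generator for comets and mRNPs, per-track and
    population statistics (speed, net direction, posterior bias, distance
    -binned frequencies, lifespans, mobile fraction, speed-subpopulation
    mixture tests), the cortical dwell-time procedure with
    location-scale t fitting, a static-rod cargo transport model
    parameterised by the mean microtubule target length, and a dynamic
    microtubule model with a dynactin anti-catastrophe positive feedback
    loop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
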