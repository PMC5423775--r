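Package: ringmotor
Title: Subunit-Poisoning Models and Hand-Over-Hand Simulation for Ring ATPases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@ringmotor.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for interpreting mixed wild-type/Walker-B-mutant
    doping experiments on hexameric AAA+ unfoldases such as VAT, the archaeal
    CDC48/p97 homologue. Provides the closed-form binomial subunit-poisoning
    activity model with a brute-force enumeration oracle, a Gillespie-style
    stochastic simulator of the sequential hand-over-hand translocation cycle
    (including stalling by catalytically dead protomers and an optional
    escape/re-engagement mechanism), reduction of ATPase and fluorescence
    unfolding assays to normalized activity curves with threshold-model and
    escape-rate fitting, geometric analyses of substrate-gripping pore-loop
    helices (rise/twist/pitch, seam detection, pore aperture, inter-ring pore
    tilt, grip extent, layer-line prediction), and synthetic-data generators so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
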