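Package: alphadosim
Title: Alpha-Particle Microdosimetry and Clonogenic Survival for
    Ra-224 Daughter-Medium Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for in vitro exposures of cell monolayers to
    culture medium charged with the short-lived alpha-emitting progeny of
    Ra-224 (Pb-212/Bi-212/Po-212), as used in diffusing alpha-emitter
    radiation therapy research.  Provides closed-form Bateman decay-chain
    kinetics with branching, a Monte-Carlo microdosimetry model that
    converts CR-39 etch-pit counts per nucleus into total alpha-particle
    nucleus hits and absorbed dose, linear dilution calibrations,
    exponential clonogenic-survival fitting (mean lethal dose D0), and a
    synthetic-data generator with known truth parameters for end-to-end
    pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
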