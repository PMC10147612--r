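Package: ferrispec
Title: Ferric-Iron Speciation, Transferrin Loading and Iron Dosimetry for
    Erythroid Cell Culture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Equilibrium speciation of ferric iron between two-site
    transferrin and hydroxypyridinone-class chelators in cell culture
    medium, including protonation-corrected conditional stability
    constants and pFe3+ computation; quasi-static simulation of medium
    speciation over a differentiation culture with a constant cellular
    iron sink; stoichiometric iron-budget and chelator-dosimetry
    calculators; hyperbolic iron/hemoglobin dose-response and Hill
    oxygen-saturation curve fitting; and seeded synthetic-data
    generators so every stage can be tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
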