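Package: bipedsim
Title: Stress-Constrained Planar Musculoskeletal Biped Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward multibody dynamics of planar, muscle-driven bipedal
    models with mid-shaft bone load recovery, beam-mechanics stress fields
    on hollow irregular cross-sections, evolutionary gait optimisation
    under a hard peak-bone-stress limit, and gait analytics (duty factor,
    Froude number, stride metrics, kinetic/potential energy phase).
    Includes deterministic model fixtures from a toy biped up to a
    Tyrannosaurus-scale stand-in, an XML model format with an importer for
    legacy GaitSym-style model files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    xml2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
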