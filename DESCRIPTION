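Package: mesogelkit
Title: Multiscale Modelling of Lamellar Liquid-Crystalline Drug-Delivery Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational workflow behind glyceryl
    monooleate (GMO) based lamellar liquid-crystalline gels loaded with a
    hydrophobic drug: Flory-Huggins interaction parameters from solubility
    parameters or cohesive-energy densities, the linear bridge to
    dissipative-particle-dynamics (DPD) repulsion parameters, a compiled
    Groot-Warren DPD engine with bead-spring amphiphile chains, mesophase
    morphology diagnostics (density fields, iso-density surfaces, static
    structure factors, interfacial enrichment), and drug-release /
    Franz-cell permeation kinetics with model selection. A synthetic-data
    module generates release curves, permeation curves and small bead-spring
    fixtures so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
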