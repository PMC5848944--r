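Package: solrel
Title: Solubility-Parameter Screening and Diffusive Release Kinetics for
    Polymer-Coated Drug Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the quantitative workflow behind polymer-coated
    nanoparticle drug-delivery experiments: Hildebrand solubility parameters
    by Small's group-contribution method with compatibility ranking of
    drug/polymer/solvent triples; Beer-Lambert calibration curves and all
    loading/capacity/cumulative-release arithmetic from UV-Vis absorbances;
    thermogravimetric coating-fraction arithmetic; a Fickian plane-sheet
    release model with an implicit finite-difference solver, an
    eigenfunction-series reference solution, and least-squares fitting of
    diffusivities and first-order release kinetics; plus seeded synthetic-data
    generators so every pipeline stage can be exercised with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
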