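Package: comdiss
Title: Dissolution Kinetics and Adsorption Inhibition Analysis for Calcium
    Oxalate Monohydrate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of calcium oxalate monohydrate (COM,
    whewellite) dissolution and its inhibition by adsorbing additives, as
    measured by the constant-composition method. Provides aqueous speciation
    of the Ca/oxalate/Na/Cl system with Davies activity corrections, relative
    undersaturation of sparingly soluble salts, power-law dissolution
    rate-law fitting in log-log space, kinetic and equilibrium Langmuir
    adsorption analysis with Gibbs free energy of adsorption, scalar
    adsorption-energy bookkeeping for electronic-structure results, and a
    synthetic-data generator with known ground truth so every pipeline stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
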