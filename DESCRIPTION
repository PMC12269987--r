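Package: nanotherm
Title: Magnetic Nanoparticle Hyperthermia with Non-Fourier Bioheat Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation toolkit for magnetic fluid hyperthermia of liver
    tumors. Computes Neel/Brownian relaxation times, linear-response-theory
    susceptibilities and volumetric power dissipation of (core-shell) ferrite
    nanoparticles in an AC magnetic field, and couples the resulting
    volumetric heat source into Pennes, single-phase-lag (Cattaneo-Vernotte)
    and dual-phase-lag bioheat equations solved with an implicit
    finite-volume scheme on a 2D cell-centered grid with perfusion,
    metabolic heat, insulated or convective (Robin) boundaries. Ships a
    catalogue of measured specific loss powers for soft/hard core-shell
    ferrites, named scenario builders for the standard liver-tissue heating
    experiments, randomized parameter perturbation for sensitivity studies,
    and reporting helpers that compare conduction models and nanoparticle
    species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
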