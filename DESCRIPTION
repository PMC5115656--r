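Package: kynredox
Title: Antioxidant Thermochemistry and Hydrogen-Transfer Kinetics of Kynurenines
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for density-functional-theory studies of
    phenolic antioxidants and kynurenine-pathway metabolites. From structured
    per-species quantum-chemistry summaries (total energies, thermal
    corrections, frontier-orbital energies, imaginary frequencies, Mulliken
    populations, Cartesian coordinates) it computes homolytic O-H bond
    dissociation enthalpies, adiabatic ionization potentials, frontier-orbital
    descriptors, spin-delocalization and charge-transfer descriptors,
    conventional transition-state-theory rate constants with Wigner tunneling,
    range-separation-parameter tuning curves for long-range-corrected
    functionals, transition-structure geometry descriptors, and the Pearson
    correlation and mean-spread summaries used to compare computed and
    experimental antioxidant activities. Ships a fixture of published
    reference tables and a synthetic-data generator with planted ground truth
    so the full pipeline is testable without running electronic-structure
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
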