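Package: pyrenav
Title: Pyrethroid Receptor Modeling in Insect Sodium Channel Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for structural analysis of pyrethroid
    insecticide binding to insect voltage-gated sodium channels. Provides the
    universal P-loop channel residue nomenclature and mapping to native
    numbering schemes, Kabsch superposition on P1 helices, a reduced
    molecular-mechanics energy model with Monte Carlo energy minimization in
    internal coordinates, multi-start ligand docking with energy-window
    ensemble filtering and contact-driven pose selection, targeted in silico
    state transformations of the pore module and voltage sensors, geometric
    interaction analysis (4 Angstrom contacts, hydrogen bonds, halogen bonds,
    salt bridges), a machine-readable atlas of knockdown-resistance (kdr)
    mutations classified against the PyR1/PyR2 receptor sites, and fully
    synthetic planted-truth channel/ligand fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    methods,
    tools,
    ChemmineR,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
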