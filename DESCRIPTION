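Package: gemcurator
Title: Reconstruction, Curation and Validation Toolkit for Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the reconstruct-curate-validate workflow used to
    build constraint-based metabolic models of metabolically versatile
    bacteria such as the purple non-sulfur bacterium Rhodopseudomonas
    palustris. Implements a stoichiometric model container with
    gene-protein-reaction (GPR) boolean logic and SBML/JSON readers and
    writers, flux balance analysis (FBA) with medium control, single-gene
    deletions, producibility (sink) tests and energy-leak detection,
    structural quality control (mass/charge balance, dead-end
    classification, orphan accounting), minimal-addition gap filling by
    mixed-integer programming, homology-transfer draft evaluation over
    BLAST cutoff grids, biomass objective construction from genome and
    proteome composition, phenotype-microarray validation with confusion
    statistics including the Matthews correlation coefficient, and
    dynamic FBA with calibration against kinetic growth data. Seeded
    generators provide synthetic networks, homology tables, phenotype
    plates and kinetic series with known ground truth for testing every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    Matrix,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
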