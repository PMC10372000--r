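Package: fluxscreen
Title: Context-Specific Metabolic Modelling and In Silico Drug Deletion Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds context-specific, flux-consistent genome-scale metabolic
    models from gene expression data and screens them for gene and drug
    essentiality. Provides flux balance analysis on a two-phase simplex,
    flux-consistency testing (FASTCC) and context extraction (FASTCORE),
    expression discretization by Gaussian mixtures, boolean
    gene-protein-reaction knockout simulation for single genes and
    multi-target drugs, and scoring of candidate drugs by efficacy against a
    cancer growth objective while protecting an ATP-maintenance objective in
    control models. Includes readers and writers for SBML Level 3 FBC and a
    compact JSON model dialect, a seeded synthetic-data generator with planted
    ground truth, and an end-to-end screening pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    mclust,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
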