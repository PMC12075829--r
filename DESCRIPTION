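Package: cdftscreen
Title: Conceptual-DFT Reactivity Descriptors and Multi-Criteria Screening of Molecular Composites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes global conceptual-DFT reactivity indices (vertical
    ionization potential and electron affinity, electronegativity, chemical
    potential, hardness, softness, electrophilicity and nucleophilicity),
    condensed Fukui functions and the condensed dual descriptor from
    three-state atomic charges, non-covalent composite binding energies and
    thermochemical consistency checks, and a rule-based ADME layer (Ertl
    topological polar surface area, drug-likeness filters, bioavailability
    score). A multi-criteria screening engine with hard filters, min-max
    normalisation, weighted ranking and Pareto-front analysis ranks candidate
    composite poses. Ships a transcribed reference dataset for six
    genistein/L-hyoscyamine composite poses together with a synthetic
    quantum-chemistry summary generator with known ground truth for testing
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    utils,
    ChemmineOB,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
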