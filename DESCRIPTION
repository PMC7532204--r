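Package: islevuln
Title: Climate-Change Vulnerability of Island Endemic Faunas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for island-scale climate-change
    vulnerability assessment of endemic species. Computes exposure as the
    mean standardized Euclidean distance (SED) between current and future
    climates over an island's grid points, sensitivity from species traits
    (habitat and dietary specialization, generation length, ecological
    redundancy via functional entities), and adaptive capacity from island
    attributes and phylogenies (surrounding land mass, protected-area
    coverage, fair-proportion evolutionary distinctiveness over a tree
    ensemble, past extinction rate). Variables are standardized to [0,1] by
    one of three schemes, oriented, aggregated into the three components,
    and combined into a single vulnerability score per island with the
    TOPSIS ideal-solution method. Includes a seeded synthetic-archipelago
    generator with plantable vulnerability structure, leave-one-variable-out
    congruence analysis, and archipelago roll-ups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    withr,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
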