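Package: fluxtree
Title: Constraint Trees for Modular Constraint-Based Metabolic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical assembly of constraint-based metabolic models via
    labeled constraint trees: directory-like structures whose leaves bind
    sparse linear expressions over a shared variable space to equality or
    interval bounds. Provides reconstruction building blocks (mass balances,
    gene knockouts, enzyme-capacity constraints, simplified resource balance
    constraints, abundance-weighted community assembly) and analysis
    algorithms (flux balance analysis, parsimonious FBA, flux variability
    analysis, production envelopes, growth-rate bisection, community
    composition screens), together with COBRA JSON and SBML/FBC model input,
    gene-protein-reaction rule handling, deterministic toy fixtures with
    analytically known optima, a brute-force LP vertex oracle for testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, Matrix, xml2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
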