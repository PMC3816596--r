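Package: eqonto
Title: Entity-Quality Phenotype Ontology Formalisation and Lethal-Phase
    Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for formalising phenotype ontologies with
    entity-quality (EQ) pattern definitions. Reads and writes OBO 1.4
    documents carrying genus-differentia patterns, performs structural
    subsumption reasoning over EQ definitions against imported entity
    ontology DAGs (GO-, CL- and PATO-style), derives human-readable
    textual definitions from entity terms, extracts paths-to-root import
    modules, and emits pre-reasoned '-simple' release artifacts. Includes
    a system for recording and reasoning about the timing and rate of
    death in mutant populations: a seven-relation Allen interval subset
    over a chain of life stages, mortality-rate ranges with the 5/50/98
    percent quantifier bands, automatic generation of lethal-phase terms,
    their classification into a nested hierarchy, and a finite-population
    model-checking oracle for validating that classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
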