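Package: fhirckg
Title: Clinical Knowledge Graphs in FHIR RDF from OMOP CDM Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compiles mappings written in a Turtle template mapping language
    (TML) into R2RML-style triples maps, executes them against an OMOP Common
    Data Model relational database to materialize a FHIR R4 RDF clinical
    knowledge graph, validates the graph against declarative FHIR shape
    constraints, and verifies transformation faithfulness by comparing SQL
    cohorts over the relational source with SPARQL cohorts over the graph.
    Ships a seedable synthetic OMOP generator with planted, known-size cohorts
    for five demonstration queries, a default OMOP-to-FHIR mapping set covering
    eleven OMOP tables and eleven FHIR resource types, and a command-line entry
    point for the end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
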