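Package: owlet
Title: Ontology Workflow Toolkit with a Built-In EL Reasoner
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for bio-ontology engineering workflows:
    reading and writing Turtle, RDF/XML and OBO flat-file (1.4 subset)
    documents; saturation-based classification and coherence checking for an
    EL-with-disjointness fragment of OWL; axiom relaxation, redundancy
    reduction and existential materialization; MIREOT and syntactic-locality
    (TOP/BOT/STAR) module extraction; whole-document merge, remove, filter,
    annotate and diff; SPARQL query and verify over the document's RDF view;
    a configurable quality-control report with severity levels and automatic
    repair; spreadsheet-template term generation; and a chainable
    command-line front end so complete release pipelines run with no
    external reasoner or service.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    utils,
    stats,
    tools,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: python3 with rdflib (for SPARQL query, verify and report)
Config/testthat/edition: 3
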