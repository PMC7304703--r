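Package: flowsynth
Title: SAT-Based Automated Composition of Scientific Workflows
Version: 0.1.0
Authors@R:
    person("Flowsynth", "Developers", email = "flowsynth@example.org",
           role = c("aut", "cre"))
Description: Automated exploration of scientific computational pipelines.
    Given a semantic domain model (an OWL ontology with an operation
    taxonomy and one or more data-characterization taxonomies, plus
    bio.tools-style JSON tool annotations) and a loose workflow
    specification (available inputs, requested outputs, natural-language
    constraint templates), flowsynth enumerates all bounded-length tool
    sequences that satisfy the specification by construction.  The
    search is encoded as propositional satisfiability and solved with a
    bundled DPLL solver; solutions are decoded into data-flow graphs and
    exported as text, Graphviz DOT, shell scripts and abstract CWL v1.2
    documents.  An independent brute-force oracle and a seeded synthetic
    domain generator support verification without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
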