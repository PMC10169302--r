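Package: ontoaudit
Title: Logical-Definition-Based Detection of Potential Missing Concepts in
    SNOMED CT-Style Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality-assurance tooling for EL-style biomedical terminologies
    such as SNOMED CT. Loads RF2 snapshots or a simple tab-separated fixture
    dialect, detects non-lattice subgraphs (concept pairs with more than one
    maximal common descendant or minimal common ancestor), filters
    hierarchically unrelated fully defined concept pairs into candidates, and
    intersects their derived logical definitions (generalization closures
    under attribute/value subsumption and property chains) to propose
    potential missing concepts with logical definitions. Includes definition
    serialization and ROUGE evaluation for pluggable concept-naming models,
    and validation of proposals against lexicon atom tables, noun-phrase
    indexes of document corpora, and newer terminology releases. Ships a
    synthetic-ontology generator with planted, recoverable missing concepts
    so the whole pipeline is testable without licensed releases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
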