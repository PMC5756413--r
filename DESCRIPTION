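Package: ontograph
Title: Labeled Graphs from OWL Ontologies by EL Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts OWL ontologies (OBO flatfile or a functional-syntax
    subset) into labeled multigraphs by inferring, with a built-in EL+
    completion-rule reasoner, the most specific existential successors of
    each class for a chosen set of object properties.  Supports a purely
    syntactic conversion mode, sub-property edge propagation, and transitive
    reduction of the resulting labeled graph.  Includes graph serializers
    (OBO, GraphML, DOT, N-Triples, TSV), graph-based semantic similarity
    (simGIC and Resnik best-match average) over annotation corpora, ROC
    evaluation of interaction prediction, and seeded synthetic-data
    generators with independent brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, xml2, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
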