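test_that("the TSV writer emits a header plus one sorted line per edge", {
  ont <- ontology(axioms = list(ax_subclass("Z", ce_some("p", "X"))))
  g <- build_graph(ont, "p")
  txt <- write_graph(g, "tsv")
  expect_identical(strsplit(txt, "\n")[[1]],
                   c("source\tlabel\ttarget", "Z\tp\tX"))
})

test_that("OBO graph output carries is_a and relationship lines", {
  ont <- read_fixture_ontology("growth_example.obo")
  g <- build_graph(ont, "part_of")
  txt <- write_graph(g, "obo")
  lines <- strsplit(txt, "\n")[[1]]
  i <- which(lines == "id: GO:0048588")
  stanza <- lines[i:(i + 2)]
  expect_true("is_a: GO:0016049" %in% stanza)
  expect_true("relationship: part_of GO:0048468" %in% stanza)
})

test_that("TSV and OBO round-trips reproduce the edge multiset", {
  for (s in 0:9) {
    ont <- random_ontology(n_classes = 10L, p_existential = 0.3,
                           p_equivalence = 0.1, seed = s)
    g <- build_graph(ont, "all", mode = "semantic")
    # TSV
    expect_identical(read_graph_tsv(write_graph(g, "tsv"))$edges, g$edges)
    # OBO: re-parse as an ontology, map axioms back to edges
    re <- parse_obo(write_graph(g, "obo"))
    keys <- vapply(re$axioms, function(ax) {
      if (ax$type == "subclass" && ontograph:::is_named(ax$sup))
        paste(ax$sub$id, "is_a", ax$sup$id, sep = " / ")
      else if (ax$type == "subclass")
        paste(ax$sub$id, ax$sup$prop, ax$sup$filler$id, sep = " / ")
      else paste(min(ax$members[[1]]$id, ax$members[[2]]$id),
                 "equivalent_to",
                 max(ax$members[[1]]$id, ax$members[[2]]$id), sep = " / ")
    }, "")
    # equivalences are written on both member stanzas; compare as sets of
    # unordered pairs
    expect_setequal(unique(keys), edge_keys(g$edges))
  }
})

test_that("writers are deterministic: write-read-write is byte-identical", {
  ont <- random_ontology(n_classes = 12L, p_existential = 0.3, seed = 21L)
  g <- build_graph(ont, "all")
  t1 <- write_graph(g, "tsv")
  t2 <- write_graph(read_graph_tsv(t1), "tsv")
  expect_identical(t1, t2)
})

test_that("N-Triples maps is_a to subClassOf and rejects unmapped labels", {
  ont <- ontology(axioms = list(
    ax_subclass("GO:1", "GO:2"),
    ax_subclass("GO:1", ce_some("part_of", "GO:3"))))
  g <- build_graph(ont, "part_of")
  nt <- write_graph(g, "ntriples")
  expect_true(grepl("rdf-schema#subClassOf", nt))
  expect_true(grepl("BFO_0000050", nt))

  ont2 <- ontology(axioms = list(ax_subclass("A", ce_some("mystery", "B"))))
  g2 <- build_graph(ont2, "mystery")
  expect_error(write_graph(g2, "ntriples", label_iri_map = character(0)),
               "no IRI mapping")
})

test_that("GraphML output is well-formed and complete", {
  skip_if_not_installed("xml2")
  ont <- read_fixture_ontology("growth_example.obo")
  g <- build_graph(ont, "part_of")
  doc <- xml2::read_xml(write_graph(g, "graphml"))
  ns <- xml2::xml_ns(doc)
  expect_identical(length(xml2::xml_find_all(doc, "//d1:node", ns)),
                   length(g$nodes))
  expect_identical(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
                   nrow(g$edges))
})

test_that("TSV reader reports malformed rows with their line number", {
  expect_error(read_graph_tsv(c("source\tlabel\ttarget", "a\tb")), "line 2")
  expect_error(read_graph_tsv("a\tb\tc"), "header")
  empty <- read_graph_tsv("source\tlabel\ttarget")
  expect_identical(nrow(empty$edges), 0L)
})

test_that("the ontology OBO writer inverts the parser on random ontologies", {
  for (s in 0:9) {
    ont <- random_ontology(n_classes = 10L, p_existential = 0.25,
                           p_equivalence = 0.15, seed = s)
    back <- parse_obo(write_obo_ontology(ont))
    expect_identical(back$classes, ont$classes)
    expect_identical(back$properties, ont$properties)
    expect_identical(axiom_keys(back), axiom_keys(ont))
    # second write is byte-identical
    expect_identical(write_obo_ontology(back), write_obo_ontology(ont))
  }
})
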