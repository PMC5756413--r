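test_that("edges go to the most specific successor only", {
  g <- build_graph(most_specific_fixture(), "p", mode = "semantic")
  expect_identical(edge_keys(g$edges), c("Y / is_a / X", "Z / p / Y"))
  # without the filter, the redundant edge to the general target survives
  g2 <- build_graph(most_specific_fixture(), "p", specific_filter = FALSE)
  expect_true("Z / p / X" %in% edge_keys(g2$edges))
})

test_that("a union axiom yields one edge per disjunct in semantic mode", {
  ont <- read_fixture_ontology("union_example.ofn")
  g <- build_graph(ont, "R", mode = "semantic")
  expect_identical(edge_keys(g$edges), c("A / R / C", "B / R / C"))
  expect_identical(nrow(build_graph(ont, "R", mode = "syntactic")$edges), 0L)
})

test_that("isolated classes stay as bare nodes", {
  ont <- ontology(classes = "W",
                  axioms = list(ax_subclass("Z", ce_some("p", "X"))))
  for (mode in c("semantic", "syntactic")) {
    g <- build_graph(ont, "p", mode = mode)
    expect_identical(edge_keys(g$edges), "Z / p / X")
    expect_true("W" %in% g$nodes)
  }
})

test_that("sub-property propagation materializes super-property edges syntactically", {
  ont <- ontology(axioms = list(
    ax_subclass("Z", ce_some("q", "X")), ax_subprop("q", "p")))
  gs <- build_graph(ont, c("p", "q"), mode = "syntactic")
  expect_setequal(edge_keys(gs$edges), c("Z / p / X", "Z / q / X"))
  # semantic mode already entails them; propagation adds nothing
  gm <- build_graph(ont, c("p", "q"), mode = "semantic")
  expect_identical(edge_keys(gm$edges), edge_keys(gs$edges))
  expect_identical(propagate_subproperty_edges(gm, ont)$edges, gm$edges)
  # with no hierarchy the graph is unchanged
  flat <- ontology(axioms = list(ax_subclass("Z", ce_some("q", "X"))),
                   properties = "p")
  gf <- build_graph(flat, c("p", "q"), mode = "syntactic")
  expect_identical(propagate_subproperty_edges(gf, flat)$edges, gf$edges)
})

test_that("reduction removes composable edges and keeps incomparable ones", {
  mk <- function(edges, axioms = list(), nodes = c("a", "b", "c")) {
    ont <- ontology(nodes, c("p", "q"), axioms)
    g <- ontograph:::new_ontology_graph(nodes, edges, "synthetic", c("p", "q"))
    list(g = g, ont = ont)
  }
  tri <- mk(ontograph:::edge_df(c("a", "b", "a"), "p", c("b", "c", "c")),
            list(ax_transitive("p")))
  expect_identical(edge_keys(transitive_reduction(tri$g, tri$ont)$edges),
                   c("a / p / b", "b / p / c"))

  # is_a absorbs on the right of a relational edge, transitive or not
  for (ax in list(list(), list(ax_transitive("p")))) {
    mix <- mk(ontograph:::edge_df(c("a", "b", "a"), c("p", "is_a", "p"),
                                  c("b", "c", "c")), ax)
    red <- transitive_reduction(mix$g, mix$ont)
    expect_identical(edge_keys(red$edges), c("a / p / b", "b / is_a / c"))
    expect_identical(graph_closure(red, mix$ont), graph_closure(mix$g, mix$ont))
  }

  # unrelated labels do not compose
  two <- mk(ontograph:::edge_df(c("a", "b", "a"), c("p", "q", "p"),
                                c("b", "c", "c")))
  expect_identical(nrow(transitive_reduction(two$g, two$ont)$edges), 3L)
})

test_that("closure follows is_a chains, transitivity and property lifting", {
  nodes <- c("a", "b", "c")
  ont1 <- ontology(nodes, "p", list())
  chain_isa <- ontograph:::new_ontology_graph(
    nodes, ontograph:::edge_df(c("a", "b"), "is_a", c("b", "c")),
    "synthetic", "p")
  expect_true("a / is_a / c" %in% edge_keys(graph_closure(chain_isa, ont1)))

  chain_p <- ontograph:::new_ontology_graph(
    nodes, ontograph:::edge_df(c("a", "b"), "p", c("b", "c")),
    "synthetic", "p")
  expect_false("a / p / c" %in% edge_keys(graph_closure(chain_p, ont1)))

  # transitive sub-property chain lifts into the super-property
  ont2 <- ontology(nodes, c("p", "q"),
                   list(ax_subprop("q", "p"), ax_transitive("q")))
  chain_q <- ontograph:::new_ontology_graph(
    nodes, ontograph:::edge_df(c("a", "b"), "q", c("b", "c")),
    "synthetic", c("p", "q"))
  keys <- edge_keys(graph_closure(chain_q, ont2))
  expect_true(all(c("a / q / c", "a / p / c") %in% keys))
})

test_that("build_graph equals the all-subclass-filter oracle on random ontologies", {
  for (s in 0:29) {
    ont <- random_ontology(n_classes = 12L, n_properties = 3L,
                           p_existential = 0.25, p_equivalence = 0.15,
                           seed = s)
    for (mode in c("semantic", "syntactic")) {
      expect_identical(build_graph(ont, "all", mode = mode)$edges,
                       oracle_graph(ont, "all", mode = mode))
    }
  }
})

test_that("reduction preserves the closure on random multigraphs", {
  for (s in 0:29) {
    rmg <- random_multigraph(n_nodes = 9L, n_edges = 20L, seed = s)
    red <- transitive_reduction(rmg$graph, rmg$ontology)
    expect_identical(graph_closure(red, rmg$ontology),
                     graph_closure(rmg$graph, rmg$ontology))
    expect_identical(graph_closure(rmg$graph, rmg$ontology),
                     oracle_closure(rmg$graph, rmg$ontology))
  }
})

test_that("the syntactic graph's content survives, retargeted, in the semantic closure", {
  for (s in 0:14) {
    ont <- random_ontology(n_classes = 12L, n_properties = 3L,
                           p_existential = 0.25, p_equivalence = 0.15,
                           seed = s)
    gsyn <- build_graph(ont, "all", mode = "syntactic")
    gsem <- build_graph(ont, "all", mode = "semantic")
    cl <- graph_closure(gsem, ont)
    tax <- classify(ont)
    rel <- gsyn$edges[!(gsyn$edges$label %in% c("is_a", "equivalent_to")), ,
                      drop = FALSE]
    for (i in seq_len(nrow(rel))) {
      zc <- unname(tax$canon[rel$source[i]])
      xc <- unname(tax$canon[rel$target[i]])
      if (is.na(zc) || is.na(xc) || zc == xc) next
      hits <- cl$target[cl$source == zc & cl$label == rel$label[i]]
      expect_true(any(vapply(hits, function(xp)
        xc %in% c(xp, tax$ancestors[[xp]]), TRUE)))
    }
  }
})

test_that("graphs are byte-stable across runs and axiom orderings", {
  ont <- random_ontology(n_classes = 15L, p_existential = 0.3,
                         p_equivalence = 0.15, seed = 11L)
  g1 <- build_graph(ont, "all", mode = "semantic", reduce = TRUE)
  shuffled <- ontology(ont$classes, ont$properties,
                       ont$axioms[rev(seq_along(ont$axioms))])
  g2 <- build_graph(shuffled, "all", mode = "semantic", reduce = TRUE)
  expect_identical(write_graph(g1, "tsv"), write_graph(g2, "tsv"))
})
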