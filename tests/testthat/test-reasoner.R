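norm_keys <- function(norm) {
  sort(vapply(norm$axioms, function(ax) paste(unlist(ax), collapse = "|"), ""),
       method = "radix")
}

test_that("normalization splits unions and passes normal axioms through", {
  u <- ontology(axioms = list(
    ax_subclass(ce_or("A", "B"), ce_some("R", "C"))))
  norm <- normalize_ontology(u)
  subs <- Filter(function(ax) ax$t == "sub", norm$axioms)
  # both disjuncts end up below the (named) restriction
  expect_identical(length(subs), 2L)
  expect_setequal(vapply(subs, function(ax) ax$a, ""), c("A", "B"))

  plain <- normalize_ontology(ontology(axioms = list(ax_subclass("A", "B"))))
  expect_identical(norm_keys(plain), "sub|A|B")
})

test_that("normalizing an equivalence definition preserves entailments", {
  # X equivalent to G and some(p, W); membership criteria flow both ways
  ont <- ontology(axioms = list(
    ax_equiv(ce_named("X"), ce_and("G", ce_some("p", "W"))),
    ax_subclass("Z", "G"),
    ax_subclass("Z", ce_some("p", "W"))))
  sat <- saturate(normalize_ontology(ont))
  expect_true("X" %in% subsumers(sat, "Z"))   # conjunction satisfied -> X
  expect_true("G" %in% subsumers(sat, "X"))   # X decomposes to its genus
  expect_identical(lapply(stats::setNames(ont$classes, ont$classes),
                          function(x) subsumers(sat, x)),
                   oracle_subsumptions(ont))
})

test_that("single completion rules fire: filler propagation and transitivity", {
  ont1 <- ontology(axioms = list(
    ax_subclass("A", ce_some("p", "B")),
    ax_subclass(ce_some("p", "B"), "C")))
  sat1 <- saturate(normalize_ontology(ont1))
  expect_true("C" %in% subsumers(sat1, "A"))

  ont2 <- ontology(axioms = list(
    ax_subclass("A", ce_some("p", "B")),
    ax_subclass("B", ce_some("p", "C")),
    ax_transitive("p")))
  sat2 <- saturate(normalize_ontology(ont2))
  expect_true(sat2$R[["p"]]["A", "C"])
})

test_that("classification reduces the taxonomy and collapses equivalences", {
  ont <- ontology(axioms = list(
    ax_subclass("A", "B"), ax_subclass("B", "C"), ax_subclass("A", "C")))
  tax <- classify(ont)
  expect_identical(tax$direct_super[["A"]], "B")
  expect_identical(tax$direct_super[["B"]], "C")

  ont2 <- ontology(axioms = list(ax_subclass("A", "B"), ax_subclass("B", "A")))
  tax2 <- classify(ont2)
  expect_identical(tax2$canonicals, "A")
  expect_setequal(tax2$members[["A"]], c("A", "B"))
})

test_that("existential queries see sub-properties and transitivity", {
  ont <- ontology(axioms = list(
    ax_subclass("Z", ce_some("q", "X")), ax_subprop("q", "p")))
  expect_identical(subclasses_of_existential(ont, "p", "X"), "Z")
  expect_identical(told_existential_subclasses(ont, "p", "X"), character(0))

  ont2 <- ontology(axioms = list(
    ax_subclass("Z", ce_some("p", "W")),
    ax_subclass("W", ce_some("p", "X")),
    ax_transitive("p")))
  expect_identical(subclasses_of_existential(ont2, "p", "X"), c("W", "Z"))

  expect_error(subclasses_of_existential(ont, "nope", "X"), "unknown")
})

test_that("told queries extract asserted patterns including conjuncts", {
  ont <- ontology(axioms = list(ax_subclass("Z", ce_some("p", "X"))))
  expect_identical(told_existential_subclasses(ont, "p", "X"), "Z")

  defn <- ontology(axioms = list(
    ax_equiv(ce_named("Z"), ce_and("G", ce_some("p", "X")))))
  expect_identical(told_existential_subclasses(defn, "p", "X"), "Z")
  # the syntactic answer agrees with the semantic one on this fixture
  expect_identical(told_existential_subclasses(defn, "p", "X"),
                   subclasses_of_existential(defn, "p", "X"))
})

test_that("saturation agrees with the naive oracle on random ontologies", {
  for (s in 0:39) {
    ont <- random_ontology(n_classes = 14L, n_properties = 3L,
                           p_existential = 0.25, p_equivalence = 0.15,
                           seed = s)
    sat <- saturate(normalize_ontology(ont))
    mine <- lapply(stats::setNames(ont$classes, ont$classes),
                   function(x) subsumers(sat, x))
    expect_identical(mine, oracle_subsumptions(ont))
  }
})

test_that("adding axioms never removes entailed subsumptions", {
  base <- random_ontology(n_classes = 12L, seed = 3L)
  bigger <- ontology(base$classes, base$properties,
                     c(base$axioms, list(ax_subclass("C:0009", "C:0002"),
                                         ax_transitive("r01"))))
  s1 <- saturate(normalize_ontology(base))
  s2 <- saturate(normalize_ontology(bigger))
  for (x in base$classes)
    expect_true(all(subsumers(s1, x) %in% subsumers(s2, x)))
})

test_that("told answers are a subset of entailed answers", {
  for (s in 0:9) {
    ont <- random_ontology(n_classes = 12L, p_existential = 0.3,
                           p_equivalence = 0.15, seed = s)
    for (p in ont$properties) {
      for (x in ont$classes) {
        expect_true(all(told_existential_subclasses(ont, p, x) %in%
                          subclasses_of_existential(ont, p, x)))
      }
    }
  }
})

test_that("saturating a saturation's materialized axioms changes nothing", {
  ont <- random_ontology(n_classes = 12L, p_existential = 0.3, seed = 5L)
  norm <- normalize_ontology(ont)
  sat <- saturate(norm)
  extra <- norm$axioms
  for (x in sat$ids) {
    for (a in sat$ids[sat$S[x, ]]) {
      if (a != x) extra[[length(extra) + 1L]] <- list(t = "sub", a = x, b = a)
    }
  }
  for (p in names(sat$R)) {
    w <- which(sat$R[[p]], arr.ind = TRUE)
    for (k in seq_len(nrow(w)))
      extra[[length(extra) + 1L]] <- list(t = "exist", a = sat$ids[w[k, 1]],
                                          r = p, b = sat$ids[w[k, 2]])
  }
  sat2 <- saturate(list(axioms = extra, classes = norm$classes,
                        properties = norm$properties))
  expect_identical(sat2$S, sat$S)
  expect_identical(sat2$R, sat$R)
})
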