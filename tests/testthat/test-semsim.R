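toy_graph <- function() {
  build_graph(read_fixture_ontology("toy_similarity.obo"), character(0))
}

toy_corpus <- function() {
  propagate_annotations(parse_gaf(readLines(fixture("toy_annotations.gaf"))),
                        toy_graph())
}

test_that("GAF parsing honours NOT qualifiers and evidence whitelists", {
  row <- function(ent, cls, ev, qual = " ", with = " ")
    paste("DB", ent, ent, qual, cls, "REF:1", ev, with, "P", "n", " ",
          "protein", "taxon:0", "20260101", "DB", sep = "\t")
  txt <- c("!gaf-version: 2.1",
           row("P1", "GO:1", "IEA"),
           row("P2", "GO:2", "IDA", qual = "NOT"),
           row("P3", "GO:3", "IGI"), row("P4", "GO:4", "IPI"),
           row("P5", "GO:5", "ISS"), row("P6", "GO:6", "IGI"))
  all_rows <- parse_gaf(txt)
  expect_setequal(names(all_rows$direct), c("P1", "P3", "P4", "P5", "P6"))
  flt <- parse_gaf(txt, c("IGI", "IPI"))
  expect_setequal(names(flt$direct), c("P3", "P4", "P6"))
  expect_identical(flt$direct$P4, "GO:4")
  expect_error(parse_gaf("a\tb\tc"), "line 1")
})

test_that("interaction pairs come out of the With/From field per code", {
  row <- function(ent, ev, with)
    paste("DB", ent, ent, " ", "GO:1", "REF:1", ev, with, "P", "n", " ",
          "protein", "taxon:0", "20260101", "DB", sep = "\t")
  txt <- c(row("P1", "IPI", "DB:P2"),
           row("P1", "IGI", "DB:P2|DB:P3"),
           row("P4", "IGI", "DB:P5,DB:P1"),
           row("P6", "IDA", "DB:P7"),
           row("P2", "IPI", "DB:P1"))  # duplicate of the first, reversed
  sets <- extract_interactions_from_gaf(txt)
  expect_identical(sets$IPI$pairs,
                   data.frame(a = "P1", b = "P2", stringsAsFactors = FALSE))
  expect_identical(nrow(sets$IGI$pairs), 4L)
  expect_true(all(c("P1", "P4") %in% sets$IGI$pairs$a))
  # empty With/From on a matching row: skipped with a warning
  expect_warning(out <- extract_interactions_from_gaf(row("P9", "IGI", " ")),
                 "skipped")
  expect_identical(nrow(out$IGI$pairs), 0L)
})

test_that("propagation treats every edge label as subclass", {
  ont <- ontology(axioms = list(ax_subclass("Z", ce_some("p", "X"))))
  g <- build_graph(ont, "p")
  corpus <- propagate_annotations(annotation_corpus(list(e = "Z")), g)
  expect_identical(corpus$propagated$e, c("X", "Z"))

  # diamond: the shared ancestor is counted once
  dia <- ontology(axioms = list(
    ax_subclass("Z", "A"), ax_subclass("Z", "B"),
    ax_subclass("A", "R"), ax_subclass("B", "R")))
  gd <- build_graph(dia, character(0))
  cd <- propagate_annotations(annotation_corpus(list(e = "Z")), gd)
  expect_identical(cd$propagated$e, c("A", "B", "R", "Z"))

  # a root annotation adds nothing; unknown classes are flagged but kept
  cr <- propagate_annotations(annotation_corpus(list(e = c("R", "XX:1"))), gd)
  expect_identical(cr$propagated$e, c("R", "XX:1"))
  expect_identical(cr$flagged, "XX:1")
})

test_that("information content matches direct counting on the toy corpus", {
  ic <- information_content(toy_corpus())
  expect_equal(unname(ic["R:0001"]), 0)
  expect_equal(unname(ic["B:0001"]), -log2(3 / 10), tolerance = 1e-12)
  expect_equal(unname(ic["B:0004"]), -log2(4 / 10), tolerance = 1e-12)
  expect_equal(unname(ic["A:0001"]), -log2(6 / 10), tolerance = 1e-12)
  # full hand-computed table
  expect_identical(names(ic), c("A:0001", "A:0002", "B:0001", "B:0002",
                                "B:0003", "B:0004", "R:0001"))
  expect_equal(unname(ic), -log2(c(6, 6, 3, 3, 3, 4, 10) / 10),
               tolerance = 1e-12)
  # an entity annotated everywhere has zero information
  all_ann <- annotation_corpus(
    stats::setNames(lapply(1:8, function(i) "c"), paste0("e", 1:8)))
  all_ann$propagated <- all_ann$direct
  expect_equal(unname(information_content(all_ann)["c"]), 0)
  # 1 of 8 entities -> 3 bits
  one <- annotation_corpus(
    stats::setNames(c(list(c("c", "d")), lapply(2:8, function(i) "d")),
                    paste0("e", 1:8)))
  one$propagated <- one$direct
  expect_equal(unname(information_content(one)["c"]), 3, tolerance = 1e-12)
})

test_that("simGIC matches hand-computed values on the toy fixture", {
  corpus <- toy_corpus()
  ic <- information_content(corpus)
  icB <- -log2(3 / 10); icA <- -log2(6 / 10)
  expect_equal(sim_gic("P01", "P02", corpus, ic), 1)
  expect_equal(sim_gic("P01", "P03", corpus, ic),
               icA / (2 * icB + icA), tolerance = 1e-12)
  expect_equal(sim_gic("P01", "P07", corpus, ic), 0)  # only the root shared
  # abstract fixture: sets {a,b,r} and {a,c,r} with ic 2,3,1,0 -> 2/6
  ab <- annotation_corpus(list(e1 = c("a", "b", "r"), e2 = c("a", "c", "r")))
  ab$propagated <- ab$direct
  expect_equal(sim_gic("e1", "e2", ab, c(a = 2, b = 3, c = 1, r = 0)), 2 / 6,
               tolerance = 1e-12)
  expect_error(sim_gic("P01", "nope", corpus, ic), "unknown entity")
})

test_that("Resnik best-match average matches the hand enumeration", {
  corpus <- toy_corpus()
  ic <- information_content(corpus)
  g <- toy_graph()
  icB <- -log2(3 / 10); icA <- -log2(6 / 10)
  expect_equal(resnik_bma("P01", "P01", corpus, ic, g), icB,
               tolerance = 1e-12)
  expect_equal(resnik_bma("P01", "P07", corpus, ic, g), 0)
  # 2x2 case: P05 {B:0001,B:0003} vs P10 {B:0002,B:0004}; all four best
  # matches hit a branch ancestor
  expect_equal(resnik_bma("P05", "P10", corpus, ic, g), icA,
               tolerance = 1e-12)
})

test_that("similarity invariants hold on the toy fixture", {
  corpus <- toy_corpus()
  ic <- information_content(corpus)
  g <- toy_graph()
  ents <- names(corpus$direct)
  for (i in seq_along(ents)) {
    for (j in seq_len(i)) {
      sij <- sim_gic(ents[i], ents[j], corpus, ic)
      expect_identical(sij, sim_gic(ents[j], ents[i], corpus, ic))
      expect_true(sij >= 0 && sij <= 1)
      expect_equal(resnik_bma(ents[i], ents[j], corpus, ic, g),
                   resnik_bma(ents[j], ents[i], corpus, ic, g))
    }
    expect_equal(sim_gic(ents[i], ents[i], corpus, ic), 1)
  }
})

test_that("information content decreases along the ancestor relation", {
  for (s in c(1L, 2L)) {
    sc <- scenario_a(seed = s, n_entities = 40L)
    corpus <- propagate_annotations(sc$corpus, sc$graph_semantic)
    ic <- information_content(corpus)
    ed <- sc$graph_semantic$edges
    for (i in seq_len(nrow(ed))) {
      s_ic <- ic[ed$source[i]]; t_ic <- ic[ed$target[i]]
      if (!is.na(s_ic) && !is.na(t_ic))
        expect_true(s_ic >= t_ic - 1e-12)
    }
  }
})

test_that("vectorized pairwise simGIC equals the per-pair definition", {
  corpus <- toy_corpus()
  ic <- information_content(corpus)
  scores <- pairwise_similarity(corpus, toy_graph(), "simgic")
  ents <- names(corpus$direct)
  pick <- list(c("P01", "P03"), c("P05", "P10"), c("P02", "P09"))
  for (pr in pick) {
    key <- paste(pr[1], pr[2], sep = "\t")
    expect_equal(unname(scores[key]), sim_gic(pr[1], pr[2], corpus, ic),
                 tolerance = 1e-12)
  }
  expect_identical(length(scores), as.integer(choose(length(ents), 2L)))
})
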