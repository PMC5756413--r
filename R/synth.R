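# Seeded synthetic-data generators: random EL+ ontologies, random labeled
# multigraphs, and a desk-scale evaluation scenario in which part of a
# property's content is reachable only through deduction.

#' Generate a random EL+ ontology
#'
#' The taxonomy is generated index-monotone (subclass edges only point
#' from higher to lower class index), which guarantees acyclicity by
#' construction; equivalence definitions (`X` equivalent to genus and one
#' existential restriction) and sub-/transitive-property axioms are then
#' layered on top.  Each (class, property) pair carries at most one
#' asserted existential restriction, the usual shape of OBO relationship
#' and definition lines.  Output is fully determined by `seed`.
#'
#' @param n_classes,n_properties Counts of classes and object properties.
#' @param p_subclass Probability of a subclass axiom per (higher, lower)
#'   class pair, scaled by 2/n_classes so expected parents per class stay
#'   stable as `n_classes` grows.
#' @param p_existential Probability that a class asserts an existential
#'   restriction for a given property.
#' @param p_equivalence Probability that a class receives an equivalence
#'   definition (genus plus existential differentia).
#' @param n_transitive,n_subproperty Numbers of transitive properties and
#'   of sub-property axioms.
#' @param seed Integer seed.
#' @return An [ontology()].
#' @export
random_ontology <- function(n_classes = 20L, n_properties = 3L,
                            p_subclass = 0.6, p_existential = 0.15,
                            p_equivalence = 0.1, n_transitive = 1L,
                            n_subproperty = 1L, seed = 0L) {
  stopifnot(n_classes >= 2L, n_properties >= 1L,
            p_subclass >= 0, p_subclass <= 1,
            p_existential >= 0, p_existential <= 1,
            p_equivalence >= 0, p_equivalence <= 1)
  if (n_subproperty > n_properties * (n_properties - 1L))
    stop("n_subproperty exceeds the number of ordered property pairs")
  if (n_transitive > n_properties)
    stop("n_transitive exceeds n_properties")
  cls <- sprintf("C:%04d", seq_len(n_classes))
  prp <- sprintf("r%02d", seq_len(n_properties))
  with_seed(seed, {
    axioms <- list()
    # taxonomy, indices decreasing source -> target
    for (i in 2:n_classes) {
      for (j in seq_len(i - 1L)) {
        if (stats::runif(1) < p_subclass * 2 / n_classes)
          axioms[[length(axioms) + 1L]] <- ax_subclass(cls[i], cls[j])
      }
    }
    # property axioms
    if (n_transitive > 0L) {
      for (p in sample(prp, n_transitive))
        axioms[[length(axioms) + 1L]] <- ax_transitive(p)
    }
    if (n_subproperty > 0L) {
      pairs <- expand.grid(sub = prp, sup = prp, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$sub != pairs$sup, , drop = FALSE]
      pick <- pairs[sample(nrow(pairs), n_subproperty), , drop = FALSE]
      for (k in seq_len(nrow(pick)))
        axioms[[length(axioms) + 1L]] <- ax_subprop(pick$sub[k], pick$sup[k])
    }
    # existential restrictions / equivalence definitions; at most one
    # asserted existential per (class, property)
    for (i in seq_len(n_classes)) {
      used <- character(0)
      if (i > 2L && stats::runif(1) < p_equivalence) {
        gw <- sample(setdiff(seq_len(i - 1L), i), 2L,
                     replace = i - 1L < 2L)
        p <- sample(prp, 1L)
        axioms[[length(axioms) + 1L]] <-
          ax_equiv(ce_named(cls[i]),
                   ce_and(cls[gw[1]], ce_some(p, cls[gw[2]])))
        used <- p
      }
      for (p in setdiff(prp, used)) {
        if (stats::runif(1) < p_existential) {
          j <- sample(setdiff(seq_len(n_classes), i), 1L)
          axioms[[length(axioms) + 1L]] <-
            ax_subclass(cls[i], ce_some(p, cls[j]))
        }
      }
    }
    ontology(cls, prp, axioms)
  })
}

#' Generate a random labeled multigraph
#'
#' Directed acyclic `is_a` skeleton (index-monotone) with additional
#' property-labeled edges; a random subset of the properties is declared
#' transitive and a random sub-property pair is asserted.  Returns both
#' the graph and a minimal [ontology()] carrying the property
#' declarations, as required by [transitive_reduction()] and
#' [graph_closure()].
#'
#' @param n_nodes,n_edges Graph size.
#' @param n_properties Number of relational edge labels.
#' @param seed Integer seed.
#' @return List with elements `graph` (an `ontology_graph`) and `ontology`.
#' @export
random_multigraph <- function(n_nodes = 10L, n_edges = 25L,
                              n_properties = 2L, seed = 0L) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  prp <- sprintf("p%d", seq_len(n_properties))
  with_seed(seed, {
    labels <- c(IS_A, prp)
    src <- integer(0); tgt <- integer(0); lab <- character(0)
    for (k in seq_len(n_edges)) {
      ij <- sample(n_nodes, 2L)
      i <- max(ij); j <- min(ij)   # edges point from higher to lower index
      src <- c(src, i); tgt <- c(tgt, j)
      lab <- c(lab, sample(labels, 1L))
    }
    ed <- edge_df(nodes[src], lab, nodes[tgt])
    ax <- list()
    n_trans <- sample(0:n_properties, 1L)
    if (n_trans > 0L) for (p in sample(prp, n_trans))
      ax[[length(ax) + 1L]] <- ax_transitive(p)
    if (n_properties >= 2L && stats::runif(1) < 0.7) {
      pq <- sample(prp, 2L)
      ax[[length(ax) + 1L]] <- ax_subprop(pq[1], pq[2])
    }
    ont <- ontology(nodes, prp, ax)
    g <- new_ontology_graph(nodes, ed, "synthetic", prp)
    list(graph = g, ontology = ont)
  })
}

#' Evaluation scenario: deduction-only property links
#'
#' Builds a small ontology in which many links of a designated property
#' (`part_of`) are asserted only indirectly: either through a sub-property
#' (`directly_part_of`, a told sub-property of `part_of`) or through
#' equivalence definitions (`X` equivalent to a genus intersected with a
#' `part_of` restriction).  A syntactic conversion restricted to `part_of`
#' therefore misses the sub-property-mediated links, while the reasoner
#' recovers them.  An annotation corpus is drawn over the ontology's
#' classes and interacting entity pairs are sampled with probability
#' logistic in the number of propagated annotation classes the pair shares
#' under the semantic graph.
#'
#' @param seed Integer seed.
#' @param n_entities Number of annotated entities.
#' @param interaction_signal Log-odds increase per shared propagated
#'   class; 0 yields a label-free null.
#' @param n_process,n_anchor,n_defined Numbers of process classes, anchor
#'   (whole) classes, and equivalence-defined classes.
#' @return List with `ontology`, `corpus` (direct annotations),
#'   `interactions` (an [interaction_set()]), `property` (the conversion
#'   property), and `graph_semantic` (the propagation graph used for
#'   sampling).
#' @export
scenario_a <- function(seed = 0L, n_entities = 200L, interaction_signal = 5,
                       n_process = 35L, n_anchor = 8L, n_defined = 10L) {
  root <- "S:0000"
  zs <- sprintf("S:1%03d", seq_len(n_process))
  ws <- sprintf("S:2%03d", seq_len(n_anchor))
  xs <- sprintf("S:3%03d", seq_len(n_defined))
  p <- "part_of"; q <- "directly_part_of"

  ont <- with_seed(seed, {
    axioms <- list(ax_subprop(q, p), ax_transitive(p))
    for (c0 in c(zs, ws)) axioms[[length(axioms) + 1L]] <- ax_subclass(c0, root)
    # sub-property-mediated links: invisible to a syntactic part_of scan
    linked <- sample(zs, ceiling(length(zs) * 0.6))
    for (z in linked) {
      w <- sample(ws, 1L)
      axioms[[length(axioms) + 1L]] <- ax_subclass(z, ce_some(q, w))
    }
    # equivalence-defined classes: genus is a process class
    for (x in xs) {
      gz <- sample(zs, 1L); w <- sample(ws, 1L)
      axioms[[length(axioms) + 1L]] <-
        ax_equiv(ce_named(x), ce_and(gz, ce_some(p, w)))
    }
    ontology(c(root, zs, ws, xs), c(p, q), axioms)
  })

  g_sem <- build_graph(ont, p, mode = "semantic")
  anc <- graph_ancestors(g_sem)

  with_seed(seed + 1L, {
    leaf <- c(zs, xs)
    direct <- lapply(seq_len(n_entities), function(i)
      sample(leaf, sample(2:4, 1L)))
    names(direct) <- sprintf("E%04d", seq_len(n_entities))
    corpus <- annotation_corpus(direct)

    prop_sets <- lapply(direct, function(cls)
      sort_ids(unlist(anc[cls], use.names = FALSE)))
    ents <- names(direct)
    cls_all <- sort_ids(unlist(prop_sets))
    M <- matrix(0L, length(ents), length(cls_all),
                dimnames = list(ents, cls_all))
    for (e in ents) M[e, prop_sets[[e]]] <- 1L
    shared <- M %*% t(M)
    pairs <- utils::combn(ents, 2L)
    ns <- shared[cbind(pairs[1, ], pairs[2, ])]
    prob <- stats::plogis(-4 + interaction_signal * (ns - mean(ns)) / max(1, stats::sd(ns)))
    hit <- stats::runif(length(prob)) < prob
    interactions <- interaction_set(pairs[1, hit], pairs[2, hit],
                                    species = "synthetic")
    list(ontology = ont, corpus = corpus, interactions = interactions,
         property = p, graph_semantic = g_sem)
  })
}
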