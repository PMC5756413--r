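# Conversion of an ontology into a labeled multigraph: taxonomy backbone
# plus most-specific existential successor edges, sub-property propagation,
# and optional transitive reduction.

edge_df <- function(source = character(0), label = character(0),
                    target = character(0)) {
  data.frame(source = as.character(source), label = as.character(label),
             target = as.character(target), stringsAsFactors = FALSE)
}

sort_edges <- function(df) {
  df <- unique(df)
  df[order(df$source, df$label, df$target, method = "radix"), ,
     drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

new_ontology_graph <- function(nodes, edges, mode, props, reduced = FALSE,
                               canon = NULL, members = NULL) {
  structure(list(nodes = sort_ids(nodes), edges = sort_edges(edges),
                 mode = mode, properties = sort_ids(props),
                 reduced = reduced, canon = canon, members = members),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  tab <- table(x$edges$label)
  cat("<ontology_graph> mode=", x$mode,
      if (x$reduced) " (reduced)" else "", ": ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  if (length(tab)) {
    for (l in names(tab)) cat("  ", l, ": ", tab[[l]], "\n", sep = "")
  }
  invisible(x)
}

#' Convert an ontology into a labeled multigraph
#'
#' The graph's backbone is the (entailed or asserted) taxonomy: `is_a`
#' edges follow the direct-superclass relation on equivalence-class
#' representatives and `equivalent_to` edges connect the members of each
#' equivalence clique.  For each requested object property `o` and each
#' class `X`, an `o`-labeled edge `Z -> X` is added exactly when `Z` is a
#' candidate `o`-successor of `X` (i.e. `Z <= some(o, X)` holds in the
#' chosen mode) and not a candidate of any direct subclass of `X` (the
#' most-specific-successor filter).  Reflexive edges and edges targeting
#' the top class are suppressed.
#'
#' In `semantic` mode candidacy is decided by the EL+ reasoner over the
#' deductive closure; in `syntactic` mode only axioms whose superclass (or
#' equivalence member) syntactically matches the existential pattern count,
#' and asserted sub-property axioms are then used to materialize implied
#' super-property edges (see [propagate_subproperty_edges()]).
#'
#' @param ont An [ontology()].
#' @param props Character vector of object-property identifiers to render
#'   as edge labels, or `"all"` for every declared property.
#' @param mode `"semantic"` (reasoner) or `"syntactic"` (asserted axioms).
#' @param reduce Apply [transitive_reduction()] to the result.
#' @param specific_filter Apply the most-specific-successor filter
#'   (disable to keep every candidate edge).
#' @param propagate In syntactic mode, materialize super-property edges.
#' @return An object of class `ontology_graph`: list with `nodes`, `edges`
#'   (data frame `source`, `label`, `target`), `mode`, `properties`,
#'   `reduced`, plus the equivalence collapse maps `canon` and `members`.
#' @examples
#' ont <- ontology(axioms = list(
#'   ax_subclass("B", "A"),
#'   ax_subclass("Z", ce_some("part_of", "B"))))
#' build_graph(ont, "part_of")
#' @export
build_graph <- function(ont, props = "all",
                        mode = c("semantic", "syntactic"),
                        reduce = FALSE, specific_filter = TRUE,
                        propagate = TRUE) {
  mode <- match.arg(mode)
  if (identical(props, "all")) props <- ont$properties
  missing_props <- setdiff(props, ont$properties)
  if (length(missing_props))
    stop("undeclared properties: ", paste(missing_props, collapse = ", "))
  props <- sort_ids(props)

  tax <- if (mode == "semantic") classify(ont) else told_taxonomy(ont)
  canonicals <- tax$canonicals

  edges <- edge_df()
  # backbone: direct is_a on representatives
  for (c0 in canonicals) {
    sup <- tax$direct_super[[c0]]
    if (length(sup))
      edges <- rbind(edges, edge_df(c0, IS_A, sup))
  }
  # equivalence cliques
  for (c0 in canonicals) {
    mem <- tax$members[[c0]]
    if (length(mem) > 1L) {
      pr <- t(utils::combn(sort_ids(mem), 2L))
      edges <- rbind(edges, edge_df(pr[, 1], EQUIV_LABEL, pr[, 2]))
    }
  }

  # candidate o-successor sets, keyed prop\rtarget, on representatives
  if (length(props) && length(canonicals)) {
    pairs <- expand.grid(prop = props, target = canonicals,
                         stringsAsFactors = FALSE)
    P <- new.env(parent = emptyenv())
    if (mode == "semantic") {
      cand <- semantic_candidates(ont, pairs)
      for (i in seq_len(nrow(pairs))) {
        z <- sort_ids(unname(tax$canon[intersect(cand[[i]], tax$classes)]))
        assign(paste(pairs$prop[i], pairs$target[i], sep = "\r"), z, envir = P)
      }
    } else {
      told <- told_candidate_map(ont, props)
      for (i in seq_len(nrow(pairs))) {
        x <- pairs$target[i]
        zs <- character(0)
        for (m in tax$members[[x]]) {
          key <- paste(pairs$prop[i], m, sep = "\r")
          if (!is.null(told[[key]])) zs <- c(zs, told[[key]])
        }
        zs <- intersect(zs, tax$classes)
        z <- sort_ids(unname(tax$canon[zs]))
        assign(paste(pairs$prop[i], pairs$target[i], sep = "\r"), z, envir = P)
      }
    }
    get_P <- function(o, x) get(paste(o, x, sep = "\r"), envir = P)
    for (o in props) {
      for (x in canonicals) {
        zs <- setdiff(get_P(o, x), x)  # no reflexive edges
        if (!length(zs)) next
        if (specific_filter) {
          for (y in tax$direct_sub[[x]]) {
            zs <- setdiff(zs, get_P(o, y))
            if (!length(zs)) break
          }
        }
        if (length(zs)) edges <- rbind(edges, edge_df(zs, o, x))
      }
    }
  }

  g <- new_ontology_graph(tax$classes, edges, mode, props,
                          canon = tax$canon, members = tax$members)
  if (propagate && mode == "syntactic")
    g <- propagate_subproperty_edges(g, ont, props)
  if (reduce) g <- transitive_reduction(g, ont)
  g
}

#' Materialize super-property edges
#'
#' For every relational edge `(X, o1, Y)` and every requested property `o2`
#' with `o1` a (reflexive-transitive) told sub-property of `o2`, ensures
#' the edge `(X, o2, Y)` is present.  In semantic mode this is a no-op:
#' entailment already produces the super-property edges.
#'
#' @param g An `ontology_graph` built without reduction.
#' @param ont The source [ontology()].
#' @param props Properties eligible as new edge labels (defaults to the
#'   graph's own property list).
#' @return The graph with super-property edges added.
#' @export
propagate_subproperty_edges <- function(g, ont, props = g$properties) {
  if (identical(g$mode, "semantic")) return(g)
  up <- property_upsets(ont)
  rel <- g$edges[!(g$edges$label %in% c(IS_A, EQUIV_LABEL)), , drop = FALSE]
  add <- edge_df()
  for (l in unique(rel$label)) {
    sup <- setdiff(intersect(up[[l]], props), l)
    if (!length(sup)) next
    sel <- rel[rel$label == l, , drop = FALSE]
    for (s in sup) add <- rbind(add, edge_df(sel$source, s, sel$target))
  }
  if (nrow(add)) g$edges <- sort_edges(rbind(g$edges, add))
  g
}
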