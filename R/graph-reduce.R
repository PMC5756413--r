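# Transitive reduction of the labeled multigraph, and the reachability
# closure it must preserve.
#
# Composition rules for edge labels along a path:
#   * is_a composes as the identity on either side of any edge;
#   * two relational edges compose only under a common super-property that
#     is declared transitive;
#   * a relational label l entails a label o exactly when l is a
#     (reflexive-transitive, told) sub-property of o.
# An is_a-only path entails is_a; a path with exactly one relational edge
# labeled l entails every o with l <= o; a path with two or more relational
# edges entails every o admitting a transitive rho with every label <= rho
# and rho <= o.

label_info <- function(ont) {
  list(up = property_upsets(ont), trans = transitive_props(ont))
}

# Is the triple (src, lab, tgt) derivable from the edges of `ed` (a data
# frame) excluding row `skip`?  Depth-first search over states
# (node, m, U) where m counts relational edges seen (capped at 2) and U is
# the intersection of the up-sets of those labels.
edge_derivable <- function(ed, src, lab, tgt, info, skip = 0L) {
  if (nrow(ed) == 0L) return(FALSE)
  keep <- seq_len(nrow(ed)) != skip & ed$label != EQUIV_LABEL
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed) == 0L) return(FALSE)
  out_idx <- split(seq_len(nrow(ed)), ed$source)

  ok_trans <- if (lab == IS_A) character(0) else
    info$trans[vapply(info$trans, function(r) lab %in% info$up[[r]], TRUE)]

  accepts <- function(m, U) {
    if (lab == IS_A) m == 0L
    else if (m == 1L) lab %in% U
    else if (m >= 2L) length(intersect(U, ok_trans)) > 0L
    else FALSE
  }

  seen <- new.env(parent = emptyenv())
  # stack of states: list(node, m, U, steps)
  stack <- list(list(node = src, m = 0L, U = character(0), steps = 0L))
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- paste(st$node, st$m, paste(st$U, collapse = "|"), sep = "\r")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    idxs <- out_idx[[st$node]]
    for (i in idxs) {
      l <- ed$label[i]; v <- ed$target[i]
      if (l == IS_A) {
        m2 <- st$m; U2 <- st$U
      } else {
        upl <- info$up[[l]]
        if (is.null(upl)) upl <- l
        if (st$m == 0L) { m2 <- 1L; U2 <- upl }
        else {
          U2 <- intersect(st$U, upl)
          if (!length(U2)) next
          m2 <- 2L
        }
      }
      if (v == tgt && st$steps + 1L >= 1L && accepts(m2, U2)) return(TRUE)
      stack[[length(stack) + 1L]] <-
        list(node = v, m = m2, U = U2, steps = st$steps + 1L)
    }
  }
  FALSE
}

#' Transitive reduction of a labeled multigraph
#'
#' Removes every edge that is derivable from the remaining edges under the
#' label-composition rules (is_a absorption, told property hierarchy,
#' declared transitivity), iterating in deterministic lexicographic edge
#' order.  The reachability closure (see [graph_closure()]) is preserved
#' exactly, and the result is minimal: removing any further edge shrinks
#' the closure.  On a pure `is_a` graph this is the textbook unique DAG
#' transitive reduction.  `equivalent_to` edges are never touched;
#' equivalence cliques must already be collapsed to representatives (as
#' [build_graph()] does).
#'
#' @param g An `ontology_graph`.
#' @param ont The source [ontology()] (supplies the property hierarchy and
#'   transitivity declarations).
#' @return The reduced graph (`reduced` flag set).
#' @export
transitive_reduction <- function(g, ont) {
  info <- label_info(ont)
  ed <- g$edges
  ord <- order(ed$source, ed$label, ed$target, method = "radix")
  ed <- ed[ord, , drop = FALSE]
  rownames(ed) <- NULL
  i <- 1L
  while (i <= nrow(ed)) {
    if (ed$label[i] != EQUIV_LABEL &&
        edge_derivable(ed, ed$source[i], ed$label[i], ed$target[i],
                       info, skip = i)) {
      ed <- ed[-i, , drop = FALSE]
      rownames(ed) <- NULL
    } else {
      i <- i + 1L
    }
  }
  g$edges <- sort_edges(ed)
  g$reduced <- TRUE
  g
}

#' Reachability closure of a labeled multigraph
#'
#' Computes, by naive fixpoint, the relation generated by the graph's
#' edges under the label-composition rules used by
#' [transitive_reduction()]: is_a chains compose; is_a absorbs on either
#' side of a relational edge; equal transitive labels compose; every
#' relational triple is lifted to all told super-properties.
#' `equivalent_to` edges do not participate.
#'
#' @inheritParams transitive_reduction
#' @return A data frame (`source`, `label`, `target`) in lexicographic
#'   order.
#' @export
graph_closure <- function(g, ont) {
  info <- label_info(ont)
  ed <- g$edges[g$edges$label != EQUIV_LABEL, , drop = FALSE]
  seen <- new.env(parent = emptyenv())
  triples <- list()
  push <- function(s, l, t) {
    key <- paste(s, l, t, sep = "\r")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      triples[[length(triples) + 1L]] <<- c(s, l, t)
      TRUE
    } else FALSE
  }
  for (i in seq_len(nrow(ed))) push(ed$source[i], ed$label[i], ed$target[i])

  repeat {
    changed <- FALSE
    cur <- triples
    # lifting
    for (tr in cur) {
      if (tr[2] != IS_A) {
        for (s in setdiff(info$up[[tr[2]]], tr[2]))
          if (push(tr[1], s, tr[3])) changed <- TRUE
      }
    }
    cur <- triples
    # index by source for the join
    by_src <- split(cur, vapply(cur, `[`, "", 1L))
    for (tr in cur) {
      nxt <- by_src[[tr[3]]]
      if (is.null(nxt)) next
      for (tr2 in nxt) {
        l1 <- tr[2]; l2 <- tr2[2]
        l <- if (l1 == IS_A && l2 == IS_A) IS_A
             else if (l1 == IS_A) l2
             else if (l2 == IS_A) l1
             else if (l1 == l2 && l1 %in% info$trans) l1
             else NA_character_
        if (!is.na(l) && push(tr[1], l, tr2[3])) changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(triples)) return(sort_edges(edge_df()))
  m <- do.call(rbind, triples)
  sort_edges(edge_df(m[, 1], m[, 2], m[, 3]))
}
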