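# Independent brute-force oracles for the property-based test suites.
# These deliberately share no code with the optimized reasoner or graph
# builder: subsumption is computed by a naive rule fixpoint over whole
# axioms (no normalization, no indexing), the graph oracle applies the
# edge definition literally (filtering against ALL subclasses of the
# target), and the closure oracle works with boolean reachability
# matrices.  Intended for small inputs only.

# Naive fixpoint state: S (named list class -> subsumer set) and R (named
# list property -> two-column character matrix of links).
oracle_state <- function(ont) {
  cls <- ont$classes
  S <- lapply(cls, function(x) c(x, OWL_THING))
  names(S) <- cls
  R <- lapply(ont$properties, function(p)
    matrix(character(0), ncol = 2L))
  names(R) <- ont$properties

  # told super-properties, reflexive-transitive, naive iteration
  up <- lapply(ont$properties, function(p) p)
  names(up) <- ont$properties
  repeat {
    ch <- FALSE
    for (ax in ont$axioms) {
      if (ax$type == "subprop") {
        add <- setdiff(up[[ax$sup]], up[[ax$sub]])
        if (length(add)) { up[[ax$sub]] <- c(up[[ax$sub]], add); ch <- TRUE }
      }
    }
    if (!ch) break
  }
  trans <- unlist(lapply(ont$axioms, function(ax)
    if (ax$type == "transitive") ax$prop else NULL))

  has_link <- function(p, a, b) {
    m <- R[[p]]
    any(m[, 1] == a & m[, 2] == b)
  }

  holds <- function(z, e) {
    switch(e$kind,
      named = e$id == OWL_THING || e$id %in% S[[z]],
      some = {
        m <- R[[e$prop]]
        ws <- m[m[, 1] == z, 2]
        any(vapply(ws, function(w) holds(w, e$filler), TRUE))
      },
      and = all(vapply(e$args, function(a) holds(z, a), TRUE)),
      or  = any(vapply(e$args, function(a) holds(z, a), TRUE))
    )
  }

  assert <- function(z, e) {
    ch <- FALSE
    if (e$kind == "named") {
      if (e$id != OWL_THING && !(e$id %in% S[[z]])) {
        S[[z]] <<- c(S[[z]], e$id); ch <- TRUE
      }
    } else if (e$kind == "and") {
      for (a in e$args) ch <- assert(z, a) || ch
    } else if (e$kind == "some") {
      if (!is_named(e$filler))
        stop("oracle supports only named existential fillers in ",
             "superclass position")
      if (!has_link(e$prop, z, e$filler$id)) {
        R[[e$prop]] <<- rbind(R[[e$prop]], c(z, e$filler$id)); ch <- TRUE
      }
    } else {
      stop("union in superclass position")
    }
    ch
  }

  repeat {
    changed <- FALSE
    for (ax in ont$axioms) {
      if (ax$type == "subclass") {
        for (z in cls) if (holds(z, ax$sub))
          changed <- assert(z, ax$sup) || changed
      } else if (ax$type == "equiv") {
        for (i in seq_along(ax$members)) for (j in seq_along(ax$members)) {
          if (i == j) next
          for (z in cls) if (holds(z, ax$members[[i]]))
            changed <- assert(z, ax$members[[j]]) || changed
        }
      }
    }
    # role hierarchy: lift links to super-properties
    for (p in names(up)) {
      for (s in setdiff(up[[p]], p)) {
        m <- R[[p]]
        for (i in seq_len(nrow(m))) {
          if (!has_link(s, m[i, 1], m[i, 2])) {
            R[[s]] <- rbind(R[[s]], m[i, ]); changed <- TRUE
          }
        }
      }
    }
    # transitivity: compose links of transitive properties
    for (p in trans) {
      m <- R[[p]]
      if (nrow(m) < 2L) next
      for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
        if (m[i, 2] == m[j, 1] && !has_link(p, m[i, 1], m[j, 2])) {
          R[[p]] <- rbind(R[[p]], c(m[i, 1], m[j, 2])); changed <- TRUE
          m <- R[[p]]
        }
      }
    }
    if (!changed) break
  }
  list(S = lapply(S, sort_ids), R = R, up = up, trans = trans)
}

#' Oracle: entailed subsumers by naive fixpoint
#'
#' Independent reference implementation of EL+ subsumption: applies the
#' inference rules directly over whole asserted axioms, testing every
#' class against every axiom each round, with no normalization or
#' indexing.  For small ontologies only.
#'
#' @param ont An [ontology()].
#' @return Named list: class id -> sorted character vector of entailed
#'   named subsumers (including the class itself and the top class).
#' @export
oracle_subsumptions <- function(ont) {
  oracle_state(ont)$S
}

#' Oracle: graph conversion by the literal definition
#'
#' Builds the conversion result directly from the definition: candidate
#' `o`-successor sets are computed for every class, and an edge `Z -> X`
#' is kept only when no proper subclass `Y` of `X` (ALL subclasses, not
#' only direct ones) also has `Z` among its candidates.  Sub-property
#' edges are then materialized in syntactic mode.  Shares no code with
#' [build_graph()].
#'
#' @param ont An [ontology()].
#' @param props Character vector of properties (or `"all"`).
#' @param mode `"semantic"` or `"syntactic"`.
#' @return A data frame of edges (`source`, `label`, `target`) in
#'   lexicographic order.
#' @export
oracle_graph <- function(ont, props = "all",
                         mode = c("semantic", "syntactic")) {
  mode <- match.arg(mode)
  if (identical(props, "all")) props <- ont$properties
  props <- sort_ids(props)
  cls <- ont$classes

  # P[[paste(o, x)]]: member-level candidate sources of member class x
  P <- new.env(parent = emptyenv())
  padd <- function(o, x, z) {
    key <- paste(o, x)
    P[[key]] <- c(P[[key]], z)
  }

  if (mode == "semantic") {
    st <- oracle_state(ont)
    subs <- st$S
    unsat <- cls[vapply(cls, function(x) OWL_NOTHING %in% subs[[x]], TRUE)]
    sats <- setdiff(cls, unsat)
    # Z <= some(o, X) iff some o-link (Z, W) with X among W's subsumers
    for (o in props) {
      m <- st$R[[o]]
      for (i in seq_len(nrow(m))) {
        for (x in intersect(subs[[m[i, 2]]], sats)) padd(o, x, m[i, 1])
      }
    }
  } else {
    # told subsumption: asserted named-named subclass/equivalence, closed
    # reflexively and transitively by repeated expansion
    subs <- lapply(cls, function(x) x)
    names(subs) <- cls
    repeat {
      ch <- FALSE
      for (ax in ont$axioms) {
        pairs <- list()
        if (ax$type == "subclass" && is_named(ax$sub) && is_named(ax$sup)) {
          pairs <- list(c(ax$sub$id, ax$sup$id))
        } else if (ax$type == "equiv") {
          nm <- vapply(Filter(is_named, ax$members), function(e) e$id, "")
          if (length(nm) >= 2L) {
            for (i in nm) for (j in nm) if (i != j)
              pairs[[length(pairs) + 1L]] <- c(i, j)
          }
        }
        for (pr in pairs) {
          for (z in cls) {
            if (pr[1] %in% subs[[z]] && !(pr[2] %in% subs[[z]])) {
              subs[[z]] <- c(subs[[z]], pr[2]); ch <- TRUE
            }
          }
        }
      }
      if (!ch) break
    }
    sats <- cls
    tops <- function(e) {
      if (e$kind == "some" && is_named(e$filler)) list(c(e$prop, e$filler$id))
      else if (e$kind == "and") {
        out <- list()
        for (a in e$args) if (a$kind == "some" && is_named(a$filler))
          out[[length(out) + 1L]] <- c(a$prop, a$filler$id)
        out
      } else list()
    }
    for (ax in ont$axioms) {
      if (ax$type == "subclass" && is_named(ax$sub)) {
        for (t in tops(ax$sup)) if (t[1] %in% props) padd(t[1], t[2], ax$sub$id)
      } else if (ax$type == "equiv") {
        nm <- vapply(Filter(is_named, ax$members), function(e) e$id, "")
        for (m in ax$members) for (t in tops(m)) for (z in nm)
          if (t[1] %in% props) padd(t[1], t[2], z)
      }
    }
  }

  # equivalence collapse: representative = lexicographic minimum
  canon <- vapply(sats, function(x) {
    eq <- sats[vapply(sats, function(y)
      (x %in% subs[[y]]) && (y %in% subs[[x]]), TRUE)]
    min(eq)
  }, "")
  reps <- sort_ids(unname(canon))

  # clique-level candidate set on representatives; reflexive candidates
  # stay in the set (they participate in the filter) and are only dropped
  # when edges are emitted
  cand_set <- function(o, x) {
    zs <- character(0)
    for (xm in sats[canon == x]) {
      key <- paste(o, xm)
      if (!is.null(P[[key]])) zs <- c(zs, P[[key]])
    }
    zs <- intersect(zs, sats)
    sort_ids(unname(canon[zs]))
  }

  # all proper canonical subclasses of representative x
  subclasses_of <- function(x) {
    below <- sats[vapply(sats, function(y)
      x %in% unname(canon[intersect(subs[[y]], sats)]), TRUE)]
    sort_ids(setdiff(unname(canon[below]), x))
  }

  src <- character(0); lab <- character(0); tgt <- character(0)
  anc_of <- function(x)
    sort_ids(setdiff(unname(canon[intersect(subs[[x]], sats)]), x))
  for (x in reps) {
    a <- anc_of(x)
    direct <- a[vapply(a, function(s)
      !any(vapply(setdiff(a, s), function(s2) s %in% anc_of(s2), TRUE)), TRUE)]
    if (length(direct)) {
      src <- c(src, rep(x, length(direct)))
      lab <- c(lab, rep("is_a", length(direct)))
      tgt <- c(tgt, direct)
    }
    mem <- sort_ids(sats[canon == x])
    if (length(mem) > 1L) {
      cmb <- utils::combn(mem, 2L)
      src <- c(src, cmb[1, ]); lab <- c(lab, rep("equivalent_to", ncol(cmb)))
      tgt <- c(tgt, cmb[2, ])
    }
  }

  CS <- list()
  for (o in props) for (x in reps) CS[[paste(o, x)]] <- cand_set(o, x)
  for (o in props) {
    for (x in reps) {
      zs <- CS[[paste(o, x)]]
      for (y in subclasses_of(x)) zs <- setdiff(zs, CS[[paste(o, y)]])
      zs <- setdiff(zs, x)
      if (length(zs)) {
        src <- c(src, zs); lab <- c(lab, rep(o, length(zs)))
        tgt <- c(tgt, rep(x, length(zs)))
      }
    }
  }

  ed <- data.frame(source = src, label = lab, target = tgt,
                   stringsAsFactors = FALSE)

  if (mode == "syntactic") {
    up <- lapply(ont$properties, function(p) p)
    names(up) <- ont$properties
    repeat {
      ch <- FALSE
      for (ax in ont$axioms) if (ax$type == "subprop") {
        add <- setdiff(up[[ax$sup]], up[[ax$sub]])
        if (length(add)) { up[[ax$sub]] <- c(up[[ax$sub]], add); ch <- TRUE }
      }
      if (!ch) break
    }
    extra <- ed[0, ]
    for (i in seq_len(nrow(ed))) {
      l <- ed$label[i]
      if (l %in% c("is_a", "equivalent_to")) next
      for (s in intersect(setdiff(up[[l]], l), props)) {
        extra <- rbind(extra, data.frame(source = ed$source[i], label = s,
                                         target = ed$target[i],
                                         stringsAsFactors = FALSE))
      }
    }
    ed <- rbind(ed, extra)
  }

  ed <- unique(ed)
  ed <- ed[order(ed$source, ed$label, ed$target, method = "radix"), ,
           drop = FALSE]
  rownames(ed) <- NULL
  ed
}

#' Oracle: reachability closure by boolean matrices
#'
#' Independent implementation of the label-composition closure of
#' [graph_closure()], organized around boolean adjacency matrices: is_a
#' reachability is a matrix transitive closure; each relational label `o`
#' collects single relational edges whose label is a told sub-property of
#' `o` (absorbed into is_a paths on either side) and, for every transitive
#' `rho` below `o`, multi-edge paths whose relational labels all lie below
#' `rho`.
#'
#' @param g An `ontology_graph`.
#' @param ont The source [ontology()].
#' @return A data frame of triples (`source`, `label`, `target`) in
#'   lexicographic order.
#' @export
oracle_closure <- function(g, ont) {
  nodes <- sort_ids(g$nodes)
  n <- length(nodes)
  empty <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  ed <- g$edges[g$edges$label != "equivalent_to", , drop = FALSE]
  adj <- function(lbl) {
    m <- empty
    sel <- ed[ed$label == lbl, , drop = FALSE]
    if (nrow(sel)) m[cbind(sel$source, sel$target)] <- TRUE
    m
  }
  tclose <- function(m, reflexive = FALSE) {
    if (reflexive) diag(m) <- TRUE
    repeat {
      m2 <- m | ((m %*% m) > 0)
      if (identical(m2, m)) break
      m <- m2
    }
    m
  }

  up <- property_upsets(ont)
  upset_of <- function(l) if (is.null(up[[l]])) l else up[[l]]
  trans <- transitive_props(ont)
  labels <- sort_ids(setdiff(ed$label, "is_a"))
  A <- adj("is_a")
  Astar <- tclose(A, reflexive = TRUE)
  out <- list()
  emit <- function(m, lbl) {
    w <- which(m, arr.ind = TRUE)
    if (nrow(w)) out[[length(out) + 1L]] <<-
      data.frame(source = nodes[w[, 1]], label = lbl,
                 target = nodes[w[, 2]], stringsAsFactors = FALSE)
  }
  emit(tclose(A), "is_a")

  for (o in sort_ids(ont$properties)) {
    below_o <- labels[vapply(labels, function(l) o %in% upset_of(l), TRUE)]
    m <- empty
    for (l in below_o) m <- m | ((Astar %*% adj(l) %*% Astar) > 0)
    for (rho in trans) {
      if (!(o %in% upset_of(rho))) next
      below_rho <- labels[vapply(labels, function(l) rho %in% upset_of(l), TRUE)]
      if (!length(below_rho)) next
      B <- empty
      for (l in below_rho) B <- B | adj(l)
      step <- (Astar %*% B %*% Astar) > 0
      m <- m | tclose(step)
    }
    emit(m, o)
  }
  if (!length(out))
    return(data.frame(source = character(0), label = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$source, res$label, res$target, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
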