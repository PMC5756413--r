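# EL+ deductive engine: structural normalization followed by
# completion-rule saturation.  Supported logic: atomic subsumption,
# conjunction, existential restriction, role hierarchies, transitivity
# (encoded as r o r <= r), plus unions restricted to the subclass side
# (compiled away by splitting).

# ---- normalization ---------------------------------------------------------

# Normal forms (plain lists):
#   list(t="sub",    a, b)        A <= B
#   list(t="conj",   a1, a2, b)   A1 n A2 <= B
#   list(t="exist",  a, r, b)     A <= some(r, B)
#   list(t="rexist", r, a, b)     some(r, A) <= B
#   list(t="subprop", r, s)       r <= s
#   list(t="trans",  r)           r o r <= r

#' Normalize an ontology to EL+ normal forms
#'
#' Rewrites every axiom into the five EL normal forms over named classes,
#' introducing deterministic fresh names (prefix `.N`) as full definitions
#' of complex sub-expressions.  Equivalence axioms are split into mutual
#' subsumptions; unions on the subclass side are split into one axiom per
#' disjunct.  Entailments between original named classes are preserved.
#'
#' @param ont An [ontology()].
#' @param strict If `TRUE`, a union in an illegal position raises an error.
#' @return A list with elements `axioms` (normalized axioms), `classes`
#'   (all named ids including fresh ones), `properties`, and `fresh`
#'   (named character map from expression key to fresh id).
#' @export
normalize_ontology <- function(ont, strict = TRUE) {
  out <- list()
  fresh <- character(0)   # expr_key -> fresh id
  counter <- 0L
  extra_classes <- character(0)

  emit <- function(ax) out[[length(out) + 1L]] <<- ax

  # Returns a named id N with axioms making N a full definition of `e`
  # (N <= e and e <= N entailed).  Memoized on the expression key.
  name_of <- function(e) {
    if (is_named(e)) return(e$id)
    key <- expr_key(e)
    if (!is.na(fresh[key])) return(unname(fresh[key]))
    counter <<- counter + 1L
    nm <- paste0(".N", counter)
    fresh[key] <<- nm
    extra_classes <<- c(extra_classes, nm)
    if (e$kind == "some") {
      f <- name_of(e$filler)
      emit(list(t = "exist", a = nm, r = e$prop, b = f))   # N <= some(r,F)
      emit(list(t = "rexist", r = e$prop, a = f, b = nm))  # some(r,F) <= N
    } else if (e$kind == "and") {
      parts <- vapply(e$args, name_of, "")
      for (p in parts) emit(list(t = "sub", a = nm, b = p)) # N <= each conjunct
      # chain of binary conjunctions: A1 n A2 <= M2, M2 n A3 <= M3, ...
      acc <- parts[1]
      for (i in seq_along(parts)[-1]) {
        tgt <- if (i == length(parts)) nm else {
          counter <<- counter + 1L
          mid <- paste0(".N", counter)
          extra_classes <<- c(extra_classes, mid)
          mid
        }
        emit(list(t = "conj", a1 = acc, a2 = parts[i], b = tgt))
        acc <- tgt
      }
    } else {
      stop("union may not occur below the top level of a subclass side")
    }
    nm
  }

  add_subclass <- function(subE, supE) {
    if (subE$kind == "or") {
      for (d in subE$args) add_subclass(d, supE)
      return(invisible())
    }
    if (expr_has_or(subE) || expr_has_or(supE)) {
      if (strict) stop("union in an unsupported position")
      return(invisible())
    }
    emit(list(t = "sub", a = name_of(subE), b = name_of(supE)))
  }

  for (ax in ont$axioms) {
    if (ax$type == "subclass") {
      add_subclass(ax$sub, ax$sup)
    } else if (ax$type == "equiv") {
      for (i in seq_along(ax$members)) {
        for (j in seq_along(ax$members)) {
          if (i != j) add_subclass(ax$members[[i]], ax$members[[j]])
        }
      }
    } else if (ax$type == "subprop") {
      emit(list(t = "subprop", r = ax$sub, s = ax$sup))
    } else if (ax$type == "transitive") {
      emit(list(t = "trans", r = ax$prop))
    }
  }

  list(axioms = out,
       classes = sort_ids(c(ont$classes, extra_classes)),
       properties = sort_ids(ont$properties),
       fresh = fresh)
}

# ---- saturation ------------------------------------------------------------

#' Saturate a normalized axiom set
#'
#' Applies the EL+ completion rules to a fixpoint: initialization
#' (`X <= X`, `X <= Thing`), atomic subsumption, conjunction, existential
#' introduction, existential-filler propagation, role hierarchy,
#' transitivity, and bottom propagation along links.  The result records,
#' for every named class (original or fresh), the full set of entailed
#' named subsumers, and for every property the set of entailed links.
#'
#' @param norm Output of [normalize_ontology()], or a list with the same
#'   shape (`axioms`, `classes`, `properties`).
#' @return An object of class `el_saturation`: list with `ids`, `S`
#'   (logical subsumption matrix, `S[x, a]` means `a` subsumes `x`), and
#'   `R` (named list of logical link matrices per property).
#' @export
saturate <- function(norm) {
  ids <- sort_ids(c(norm$classes, OWL_THING, OWL_NOTHING))
  nn <- length(ids)
  idx <- stats::setNames(seq_len(nn), ids)
  S <- diag(nn) > 0
  dimnames(S) <- list(ids, ids)
  S[, idx[[OWL_THING]]] <- TRUE
  props <- sort_ids(norm$properties)
  R <- lapply(props, function(p)
    matrix(FALSE, nn, nn, dimnames = list(ids, ids)))
  names(R) <- props
  bot <- idx[[OWL_NOTHING]]

  axs <- norm$axioms
  repeat {
    before <- sum(S) + sum(vapply(R, sum, 0))
    for (ax in axs) {
      switch(ax$t,
        sub = {
          S[, idx[[ax$b]]] <- S[, idx[[ax$b]]] | S[, idx[[ax$a]]]
        },
        conj = {
          S[, idx[[ax$b]]] <- S[, idx[[ax$b]]] |
            (S[, idx[[ax$a1]]] & S[, idx[[ax$a2]]])
        },
        exist = {
          R[[ax$r]][, idx[[ax$b]]] <- R[[ax$r]][, idx[[ax$b]]] | S[, idx[[ax$a]]]
        },
        rexist = {
          hit <- (R[[ax$r]] %*% S[, idx[[ax$a]]]) > 0
          S[, idx[[ax$b]]] <- S[, idx[[ax$b]]] | hit
        },
        subprop = {
          R[[ax$s]] <- R[[ax$s]] | R[[ax$r]]
        },
        trans = {
          R[[ax$r]] <- R[[ax$r]] | ((R[[ax$r]] %*% R[[ax$r]]) > 0)
        }
      )
    }
    if (any(S[, bot])) {
      for (p in props) S[, bot] <- S[, bot] | ((R[[p]] %*% S[, bot]) > 0)
    }
    after <- sum(S) + sum(vapply(R, sum, 0))
    if (after == before) break
  }
  structure(list(ids = ids, S = S, R = R), class = "el_saturation")
}

#' @export
print.el_saturation <- function(x, ...) {
  cat("<el_saturation> ", length(x$ids), " classes, ",
      length(x$R), " properties, ", sum(x$S), " subsumption entries\n",
      sep = "")
  invisible(x)
}

#' Entailed subsumers of a class
#'
#' @param sat An `el_saturation` from [saturate()].
#' @param x Class identifier.
#' @param named_only Drop fresh (internal) names from the answer.
#' @return Character vector of subsumer identifiers (includes `x` itself
#'   and the top class).
#' @export
subsumers <- function(sat, x, named_only = TRUE) {
  out <- sat$ids[sat$S[x, ]]
  if (named_only) out <- out[!is_fresh_id(out)]
  out
}

is_unsat <- function(sat, x) sat$S[x, OWL_NOTHING]

# ---- taxonomy --------------------------------------------------------------

# Build a taxonomy view from a full subsumption relation given as a logical
# matrix `M` over declared class ids (M[x, y]: y subsumes x; reflexive).
taxonomy_from_subsumption <- function(M, unsat = character(0)) {
  ids <- rownames(M)
  sats <- setdiff(ids, unsat)
  M <- M[sats, sats, drop = FALSE]
  mutual <- M & t(M)
  canon <- vapply(sats, function(x) min(sats[mutual[x, ]]), "")
  canonicals <- sort_ids(canon)
  members <- split(sats, canon)[canonicals]

  # strict canonical ancestors of each canonical class
  anc <- lapply(canonicals, function(c0) {
    sup <- sats[M[c0, ]]
    setdiff(sort_ids(canon[sup]), c0)
  })
  names(anc) <- canonicals

  direct_super <- lapply(canonicals, function(c0) {
    a <- anc[[c0]]
    keep <- vapply(a, function(s) !any(vapply(setdiff(a, s),
      function(s2) s %in% anc[[s2]], TRUE)), TRUE)
    a[keep]
  })
  names(direct_super) <- canonicals

  direct_sub <- lapply(canonicals, function(c0) character(0))
  names(direct_sub) <- canonicals
  for (c0 in canonicals) {
    for (s in direct_super[[c0]]) direct_sub[[s]] <- c(direct_sub[[s]], c0)
  }
  direct_sub <- lapply(direct_sub, sort_ids)

  structure(list(classes = sats, canonicals = canonicals, canon = canon,
                 members = members, ancestors = anc,
                 direct_super = direct_super, direct_sub = direct_sub,
                 unsatisfiable = sort_ids(unsat)),
            class = "el_taxonomy")
}

#' @export
print.el_taxonomy <- function(x, ...) {
  cat("<el_taxonomy> ", length(x$canonicals), " canonical classes (",
      length(x$classes), " named), ", length(x$unsatisfiable),
      " unsatisfiable\n", sep = "")
  invisible(x)
}

# Subsumption matrix over declared classes from a saturation.
subsumption_matrix <- function(sat, classes) {
  M <- sat$S[classes, classes, drop = FALSE]
  M
}

#' Classify an ontology
#'
#' Computes the entailed taxonomy: equivalence classes of named classes
#' under mutual subsumption (collapsed to the lexicographically smallest
#' representative), the direct-superclass relation (transitive reduction of
#' the entailed partial order on representatives), and the set of
#' unsatisfiable classes.
#'
#' @param ont An [ontology()].
#' @return An object of class `el_taxonomy` with elements `classes`,
#'   `canonicals`, `canon` (member to representative map), `members`,
#'   `ancestors`, `direct_super`, `direct_sub`, `unsatisfiable`.
#' @export
classify <- function(ont) {
  sat <- saturate(normalize_ontology(ont))
  cls <- ont$classes
  if (length(cls) == 0L) return(taxonomy_from_subsumption(
    matrix(TRUE, 0, 0, dimnames = list(character(0), character(0)))))
  unsat <- cls[vapply(cls, function(x) is_unsat(sat, x), TRUE)]
  taxonomy_from_subsumption(subsumption_matrix(sat, cls), unsat)
}

#' Told (asserted) taxonomy
#'
#' Taxonomy computed from asserted subclass and equivalence axioms between
#' named classes only, without deduction; the direct-superclass relation is
#' still the transitive reduction of the asserted reachability.
#'
#' @param ont An [ontology()].
#' @return An `el_taxonomy`, as for [classify()].
#' @export
told_taxonomy <- function(ont) {
  cls <- ont$classes
  nn <- length(cls)
  M <- diag(nn) > 0
  dimnames(M) <- list(cls, cls)
  for (ax in ont$axioms) {
    if (ax$type == "subclass" && is_named(ax$sub) && is_named(ax$sup)) {
      M[ax$sub$id, ax$sup$id] <- TRUE
    } else if (ax$type == "equiv") {
      nm <- Filter(is_named, ax$members)
      ids <- vapply(nm, function(e) e$id, "")
      for (a in ids) for (b in ids) M[a, b] <- TRUE
    }
  }
  # reflexive-transitive closure
  repeat {
    M2 <- M | ((M %*% M) > 0)
    if (identical(M2, M)) break
    M <- M2
  }
  taxonomy_from_subsumption(M)
}

# ---- existential queries ---------------------------------------------------

# Batched semantic candidate computation: one saturation answers every
# (property, target) query of a conversion run.  `pairs` is a data frame
# with columns `prop`, `target`.
semantic_candidates <- function(ont, pairs, norm = NULL) {
  if (is.null(norm)) norm <- normalize_ontology(ont)
  qn <- paste0(".Q", seq_len(nrow(pairs)))
  axs <- norm$axioms
  for (i in seq_len(nrow(pairs))) {
    o <- pairs$prop[i]; x <- pairs$target[i]
    axs[[length(axs) + 1L]] <- list(t = "exist", a = qn[i], r = o, b = x)
    axs[[length(axs) + 1L]] <- list(t = "rexist", r = o, a = x, b = qn[i])
  }
  norm2 <- list(axioms = axs, classes = c(norm$classes, qn),
                properties = norm$properties)
  sat <- saturate(norm2)
  real <- intersect(sat$ids, ont$classes)
  unsat <- real[sat$S[real, OWL_NOTHING]]
  keep <- setdiff(real, unsat)
  lapply(seq_len(nrow(pairs)), function(i) {
    ans <- keep[sat$S[keep, qn[i]]]
    sort_ids(ans)
  })
}

#' Entailed subclasses of an existential restriction
#'
#' Returns every satisfiable named class `Z` entailed to satisfy
#' `Z <= some(o, X)` (including classes equivalent to the restriction).
#' Implemented by introducing a fresh query name defined as the restriction
#' and reading its subsumees off a saturation.
#'
#' @param ont An [ontology()].
#' @param o Object-property identifier.
#' @param x Named-class identifier (the filler).
#' @return Sorted character vector of class identifiers.
#' @export
subclasses_of_existential <- function(ont, o, x) {
  if (!o %in% ont$properties) stop("unknown property: ", o)
  if (!x %in% ont$classes) stop("unknown class: ", x)
  semantic_candidates(ont, data.frame(prop = o, target = x,
                                      stringsAsFactors = FALSE))[[1]]
}

# Told candidate scan: map "prop\rtarget" -> asserted subclasses.  A class Z
# counts when an axiom asserts Z <= E or Z equivalent to E where E is
# syntactically some(o, X), or has some(o, X) as a top-level conjunct.
told_candidate_map <- function(ont, props = NULL) {
  env <- new.env(parent = emptyenv())
  add <- function(o, x, z) {
    if (!is.null(props) && !(o %in% props)) return(invisible())
    key <- paste(o, x, sep = "\r")
    env[[key]] <- c(env[[key]], z)
  }
  patterns_of <- function(e) {
    # top-level existential patterns with named fillers
    if (e$kind == "some" && is_named(e$filler)) {
      list(c(e$prop, e$filler$id))
    } else if (e$kind == "and") {
      out <- list()
      for (a in e$args) {
        if (a$kind == "some" && is_named(a$filler))
          out[[length(out) + 1L]] <- c(a$prop, a$filler$id)
      }
      out
    } else list()
  }
  for (ax in ont$axioms) {
    if (ax$type == "subclass" && is_named(ax$sub)) {
      for (p in patterns_of(ax$sup)) add(p[1], p[2], ax$sub$id)
    } else if (ax$type == "equiv") {
      named <- Filter(is_named, ax$members)
      if (length(named) == 0L) next
      zs <- vapply(named, function(e) e$id, "")
      for (m in ax$members) {
        for (p in patterns_of(m)) for (z in zs) add(p[1], p[2], z)
      }
    }
  }
  env
}

#' Asserted (told) subclasses of an existential restriction
#'
#' Purely syntactic counterpart of [subclasses_of_existential()]: returns
#' the named classes asserted (by a subclass axiom or membership in an
#' equivalence axiom) to stand under an expression syntactically equal to
#' `some(o, X)`, including the restriction occurring as a top-level
#' conjunct.  No deduction is performed.
#'
#' @inheritParams subclasses_of_existential
#' @return Sorted character vector of class identifiers.
#' @export
told_existential_subclasses <- function(ont, o, x) {
  env <- told_candidate_map(ont)
  key <- paste(o, x, sep = "\r")
  sort_ids(if (is.null(env[[key]])) character(0) else env[[key]])
}

# Reflexive-transitive closure of the told property hierarchy:
# named list prop -> sorted character vector of (reflexive) super-properties.
property_upsets <- function(ont) {
  props <- ont$properties
  up <- lapply(props, function(p) p)
  names(up) <- props
  edges <- Filter(function(ax) ax$type == "subprop", ont$axioms)
  repeat {
    changed <- FALSE
    for (ax in edges) {
      add <- setdiff(up[[ax$sup]], up[[ax$sub]])
      if (length(add)) {
        up[[ax$sub]] <- sort_ids(c(up[[ax$sub]], add))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  up
}

transitive_props <- function(ont) {
  sort_ids(vapply(Filter(function(ax) ax$type == "transitive", ont$axioms),
                  function(ax) ax$prop, ""))
}
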