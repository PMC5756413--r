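# The axiom-level ontology container.

#' Axiom constructors
#'
#' Build axioms of the supported subset: `ax_subclass(sub, sup)` a subclass
#' axiom, `ax_equiv(...)` an equivalent-classes axiom (two or more members),
#' `ax_subprop(sub, sup)` an object sub-property axiom, and
#' `ax_transitive(prop)` a transitive-property declaration.  Class arguments
#' accept expressions or bare identifier strings.
#'
#' @param sub,sup For `ax_subclass`: class expressions (or identifier
#'   strings).  For `ax_subprop`: property identifier strings.
#' @param ... Class expressions (or identifier strings), members of the
#'   equivalence axiom.
#' @param prop Property identifier string.
#' @return An axiom object (list with a `type` tag).
#' @examples
#' ax_subclass("GO:0048588", ce_some("part_of", "GO:0048468"))
#' @export
ax_subclass <- function(sub, sup) {
  structure(list(type = "subclass", sub = as_class_expr(sub),
                 sup = as_class_expr(sup)), class = "ont_axiom")
}

#' @rdname ax_subclass
#' @export
ax_equiv <- function(...) {
  members <- lapply(list(...), as_class_expr)
  if (length(members) < 2L) stop("ax_equiv() needs at least 2 members")
  structure(list(type = "equiv", members = members), class = "ont_axiom")
}

#' @rdname ax_subclass
#' @export
ax_subprop <- function(sub, sup) {
  stopifnot(is.character(sub), is.character(sup))
  structure(list(type = "subprop", sub = sub, sup = sup), class = "ont_axiom")
}

#' @rdname ax_subclass
#' @export
ax_transitive <- function(prop) {
  stopifnot(is.character(prop))
  structure(list(type = "transitive", prop = prop), class = "ont_axiom")
}

axiom_key <- function(ax) {
  switch(ax$type,
    subclass   = paste0("sub(", expr_key(ax$sub), "<", expr_key(ax$sup), ")"),
    equiv      = paste0("eq(", paste(sort_ids(vapply(ax$members, expr_key, "")),
                                     collapse = "|"), ")"),
    subprop    = paste0("subprop(", ax$sub, "<", ax$sup, ")"),
    transitive = paste0("trans(", ax$prop, ")")
  )
}

axiom_classes <- function(ax) {
  switch(ax$type,
    subclass   = c(expr_classes(ax$sub), expr_classes(ax$sup)),
    equiv      = unlist(lapply(ax$members, expr_classes)),
    subprop    = character(0),
    transitive = character(0)
  )
}

axiom_props <- function(ax) {
  switch(ax$type,
    subclass   = c(expr_props(ax$sub), expr_props(ax$sup)),
    equiv      = unlist(lapply(ax$members, expr_props)),
    subprop    = c(ax$sub, ax$sup),
    transitive = ax$prop
  )
}

#' Construct an ontology
#'
#' An ontology is a set of named classes, a set of object properties, and a
#' list of axioms.  Identifiers used in axioms but not declared are
#' auto-declared.  The reserved top and bottom classes are never listed
#' among `classes`.
#'
#' @param classes Character vector of declared class identifiers.
#' @param properties Character vector of declared object-property
#'   identifiers.
#' @param axioms List of axioms built with [ax_subclass()] and friends.
#' @param warnings Character vector of parser/validation warning records.
#' @return An object of class `ontology` with elements `classes`,
#'   `properties`, `axioms`, `warnings`.
#' @export
ontology <- function(classes = character(0), properties = character(0),
                     axioms = list(), warnings = character(0)) {
  used_cls <- unlist(lapply(axioms, axiom_classes))
  used_prp <- unlist(lapply(axioms, axiom_props))
  classes <- setdiff(sort_ids(c(classes, used_cls)), c(OWL_THING, OWL_NOTHING))
  properties <- setdiff(sort_ids(c(properties, used_prp)),
                        c(IS_A, EQUIV_LABEL))
  structure(list(classes = classes, properties = properties,
                 axioms = axioms, warnings = warnings),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", length(x$classes), " classes, ",
      length(x$properties), " properties, ",
      length(x$axioms), " axioms\n", sep = "")
  if (length(x$warnings))
    cat("  ", length(x$warnings), " warning record(s)\n", sep = "")
  invisible(x)
}

#' Validate an ontology
#'
#' Checks the structural invariants of the supported subset and returns a
#' data frame of diagnostics (zero rows when the ontology is well formed):
#' unions may appear only as the whole subclass side of a subclass axiom;
#' equivalence members must be pairwise distinct; identifiers must be
#' non-empty; properties must not collide with the reserved edge labels.
#'
#' @param ont An [ontology()].
#' @return A data frame with columns `severity`, `message`, `location`.
#' @export
validate_ontology <- function(ont) {
  sev <- character(0); msg <- character(0); loc <- character(0)
  note <- function(s, m, l) {
    sev <<- c(sev, s); msg <<- c(msg, m); loc <<- c(loc, l)
  }
  if (any(!nzchar(ont$classes)))
    note("error", "empty class identifier", "classes")
  if (any(ont$properties %in% c(IS_A, EQUIV_LABEL)))
    note("error", "property collides with a reserved edge label", "properties")
  for (i in seq_along(ont$axioms)) {
    ax <- ont$axioms[[i]]
    where <- paste0("axiom ", i)
    if (ax$type == "subclass") {
      if (expr_has_or(ax$sub, top_ok = TRUE))
        note("error", "union nested below the top level of a subclass side", where)
      if (expr_has_or(ax$sup))
        note("error", "union in superclass position", where)
    } else if (ax$type == "equiv") {
      keys <- vapply(ax$members, expr_key, "")
      if (anyDuplicated(keys))
        note("error", "duplicate members in an equivalence axiom", where)
      if (any(vapply(ax$members, expr_has_or, TRUE)))
        note("error", "union in an equivalence axiom", where)
    }
  }
  data.frame(severity = sev, message = msg, location = loc,
             stringsAsFactors = FALSE)
}
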