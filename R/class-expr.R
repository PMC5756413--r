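# Class expressions of the supported OWL subset: named classes, existential
# restrictions, intersections, and unions (unions only on the subclass side
# of an axiom; enforced by validate_ontology()).

#' Class expression constructors
#'
#' Build class expressions of the supported description-logic subset:
#' `ce_named(id)` a named class, `ce_some(prop, filler)` an existential
#' restriction, `ce_and(...)` an intersection, `ce_or(...)` a union
#' (allowed only in subclass position).  `ce_and()`/`ce_or()` accept
#' expressions or bare identifier strings (coerced with `ce_named()`).
#'
#' @param id Class identifier string.
#' @param prop Object property identifier string.
#' @param filler Class expression (or identifier string) under the
#'   existential restriction.
#' @param ... Two or more class expressions (or identifier strings).
#' @return A class expression object (list with a `kind` tag).
#' @examples
#' ce_some("part_of", ce_named("GO:0048468"))
#' ce_and("GO:0016049", ce_some("part_of", "GO:0048468"))
#' @export
ce_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(kind = "named", id = id), class = "class_expr")
}

as_class_expr <- function(x) {
  if (inherits(x, "class_expr")) x else ce_named(x)
}

#' @rdname ce_named
#' @export
ce_some <- function(prop, filler) {
  stopifnot(is.character(prop), length(prop) == 1L, nzchar(prop))
  structure(list(kind = "some", prop = prop, filler = as_class_expr(filler)),
            class = "class_expr")
}

#' @rdname ce_named
#' @export
ce_and <- function(...) {
  args <- lapply(list(...), as_class_expr)
  if (length(args) < 2L) stop("ce_and() needs at least 2 conjuncts")
  structure(list(kind = "and", args = args), class = "class_expr")
}

#' @rdname ce_named
#' @export
ce_or <- function(...) {
  args <- lapply(list(...), as_class_expr)
  if (length(args) < 2L) stop("ce_or() needs at least 2 disjuncts")
  structure(list(kind = "or", args = args), class = "class_expr")
}

# Canonical string form.  Arguments of and/or are sorted, so structural
# equality is insensitive to conjunct order.
expr_key <- function(e) {
  switch(e$kind,
    named = e$id,
    some  = paste0("some(", e$prop, ",", expr_key(e$filler), ")"),
    and   = paste0("and(", paste(sort_ids(vapply(e$args, expr_key, "")),
                                 collapse = "|"), ")"),
    or    = paste0("or(", paste(sort_ids(vapply(e$args, expr_key, "")),
                                collapse = "|"), ")"),
    stop("unknown expression kind: ", e$kind)
  )
}

expr_equal <- function(a, b) identical(expr_key(a), expr_key(b))

is_named <- function(e) identical(e$kind, "named")

# All class identifiers mentioned in an expression.
expr_classes <- function(e) {
  switch(e$kind,
    named = e$id,
    some  = expr_classes(e$filler),
    and   = unlist(lapply(e$args, expr_classes)),
    or    = unlist(lapply(e$args, expr_classes))
  )
}

# All property identifiers mentioned in an expression.
expr_props <- function(e) {
  switch(e$kind,
    named = character(0),
    some  = c(e$prop, expr_props(e$filler)),
    and   = unlist(lapply(e$args, expr_props)),
    or    = unlist(lapply(e$args, expr_props))
  )
}

# TRUE if an `or` occurs anywhere in the expression.
expr_has_or <- function(e, top_ok = FALSE) {
  switch(e$kind,
    named = FALSE,
    some  = expr_has_or(e$filler),
    and   = any(vapply(e$args, expr_has_or, TRUE)),
    or    = !top_ok || any(vapply(e$args, expr_has_or, TRUE))
  )
}

#' @export
format.class_expr <- function(x, ...) {
  switch(x$kind,
    named = x$id,
    some  = paste0(x$prop, " some ", format(x$filler)),
    and   = paste0("(", paste(vapply(x$args, format, ""), collapse = " and "), ")"),
    or    = paste0("(", paste(vapply(x$args, format, ""), collapse = " or "), ")")
  )
}

#' @export
print.class_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
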