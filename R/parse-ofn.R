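# Reader for a subset of the OWL functional-style syntax.

ofn_tokenize <- function(text) {
  text <- paste(text, collapse = "\n")
  # strip line comments
  text <- gsub("(?m)^\\s*#.*$", "", text, perl = TRUE)
  pat <- "<[^>]*>|[()=]|[^\\s()=]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(text, list(m))[[1]]
}

ofn_name <- function(tok) {
  if (startsWith(tok, "<") && endsWith(tok, ">"))
    curie_from_iri(substr(tok, 2L, nchar(tok) - 1L))
  else if (tok == "owl:Thing") OWL_THING
  else if (tok == "owl:Nothing") OWL_NOTHING
  else sub("^:", "", tok)
}

#' Parse OWL functional-style syntax (subset)
#'
#' Supports `Declaration` (Class, ObjectProperty), `SubClassOf`,
#' `EquivalentClasses`, `SubObjectPropertyOf`, `TransitiveObjectProperty`,
#' and the class constructors `ObjectSomeValuesFrom`,
#' `ObjectIntersectionOf`, `ObjectUnionOf`.  `Prefix` and `Ontology`
#' wrappers are recognized; any other axiom type is skipped and recorded in
#' `warnings`.  Full IRIs in angle brackets are converted to CURIEs.
#'
#' @param text Document as a single string or character vector of lines.
#' @param strict If `TRUE`, unsupported axiom types raise an error instead
#'   of a warning record.
#' @return An [ontology()].
#' @export
parse_ofn <- function(text, strict = FALSE) {
  toks <- ofn_tokenize(text)
  pos <- 1L
  n <- length(toks)
  classes <- character(0); properties <- character(0)
  axioms <- list(); warnings <- character(0)

  peek <- function() if (pos <= n) toks[pos] else NA_character_
  advance <- function() {
    t <- peek(); pos <<- pos + 1L
    if (is.na(t)) stop("unexpected end of input (unbalanced parentheses?)")
    t
  }
  expect <- function(what) {
    t <- advance()
    if (t != what) stop("expected '", what, "' but found '", t, "'")
    t
  }

  # Skip a balanced parenthesized group whose head token was just consumed.
  skip_group <- function() {
    expect("(")
    depth <- 1L
    while (depth > 0L) {
      t <- advance()
      if (t == "(") depth <- depth + 1L
      if (t == ")") depth <- depth - 1L
    }
  }

  parse_class_expr <- function() {
    t <- advance()
    if (t == "ObjectSomeValuesFrom") {
      expect("(")
      prop <- ofn_name(advance())
      properties <<- c(properties, prop)
      filler <- parse_class_expr()
      expect(")")
      ce_some(prop, filler)
    } else if (t == "ObjectIntersectionOf" || t == "ObjectUnionOf") {
      expect("(")
      args <- list()
      while (peek() != ")") args[[length(args) + 1L]] <- parse_class_expr()
      expect(")")
      if (t == "ObjectIntersectionOf") do.call(ce_and, args)
      else do.call(ce_or, args)
    } else if (t %in% c("(", ")")) {
      stop("unexpected '", t, "' in class expression")
    } else {
      ce_named(ofn_name(t))
    }
  }

  while (!is.na(peek())) {
    head <- advance()
    if (head %in% c("Prefix", "Import", "Annotation", "AnnotationAssertion")) {
      skip_group()
    } else if (head == "Ontology") {
      expect("(")
      # optional ontology IRI tokens before the first axiom head
      while (!is.na(peek()) && peek() != ")" &&
             !grepl("^[A-Z]", peek())) advance()
    } else if (head == ")") {
      next  # closing of the Ontology( wrapper
    } else if (head == "Declaration") {
      expect("(")
      kind <- advance()
      expect("(")
      id <- ofn_name(advance())
      expect(")")
      expect(")")
      if (kind == "Class") classes <- c(classes, id)
      else if (kind == "ObjectProperty") properties <- c(properties, id)
      else warnings <- c(warnings, paste0("skipped declaration of ", kind))
    } else if (head == "SubClassOf") {
      expect("(")
      sub <- parse_class_expr(); sup <- parse_class_expr()
      expect(")")
      if (expr_has_or(sup))
        stop("union in superclass position: ", format(sup))
      axioms[[length(axioms) + 1L]] <- ax_subclass(sub, sup)
    } else if (head == "EquivalentClasses") {
      expect("(")
      members <- list()
      while (peek() != ")") members[[length(members) + 1L]] <- parse_class_expr()
      expect(")")
      axioms[[length(axioms) + 1L]] <- do.call(ax_equiv, members)
    } else if (head == "SubObjectPropertyOf") {
      expect("(")
      a <- ofn_name(advance()); b <- ofn_name(advance())
      expect(")")
      axioms[[length(axioms) + 1L]] <- ax_subprop(a, b)
    } else if (head == "TransitiveObjectProperty") {
      expect("(")
      p <- ofn_name(advance())
      expect(")")
      axioms[[length(axioms) + 1L]] <- ax_transitive(p)
    } else {
      if (strict) stop("unsupported axiom type: ", head)
      warnings <- c(warnings, paste0("skipped unsupported axiom: ", head))
      if (identical(peek(), "(")) skip_group()
    }
  }

  ontology(classes, properties, axioms, warnings = warnings)
}
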