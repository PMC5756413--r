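# Serializers for generated graphs and the ontology model.  All writers
# emit UTF-8 text with LF line endings and lexicographically sorted
# content, so output is byte-stable across runs.

GRAPH_FORMATS <- c("obo", "graphml", "dot", "ntriples", "tsv")

# Known OBO Relation Ontology PURLs for common relation labels.
DEFAULT_LABEL_IRIS <- c(
  part_of               = "http://purl.obolibrary.org/obo/BFO_0000050",
  has_part              = "http://purl.obolibrary.org/obo/BFO_0000051",
  occurs_in             = "http://purl.obolibrary.org/obo/BFO_0000066",
  regulates             = "http://purl.obolibrary.org/obo/RO_0002211",
  negatively_regulates  = "http://purl.obolibrary.org/obo/RO_0002212",
  positively_regulates  = "http://purl.obolibrary.org/obo/RO_0002213"
)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Serialize a graph
#'
#' Writes an `ontology_graph` in one of five formats: `"obo"` (one
#' `[Term]` stanza per node with `is_a:`, `relationship:` and
#' `equivalent_to:` lines), `"graphml"`, `"dot"` (GraphViz structure,
#' no layout), `"ntriples"` (`is_a` mapped to `rdfs:subClassOf`,
#' `equivalent_to` to `owl:equivalentClass`, other labels resolved through
#' `label_iri_map`), or `"tsv"` (three columns with a header line).
#'
#' @param g An `ontology_graph`.
#' @param format One of `"obo"`, `"graphml"`, `"dot"`, `"ntriples"`,
#'   `"tsv"`.
#' @param file Optional path; when given the text is written there and the
#'   path returned invisibly.
#' @param label_iri_map Named character vector mapping relational edge
#'   labels to predicate IRIs for N-Triples output.  CURIE-shaped labels
#'   are resolved with [iri_from_curie()]; a handful of common relation
#'   names have built-in Relation Ontology PURLs; any other unmapped label
#'   is an error.
#' @param include_equivalences Emit `equivalent_to` edges.
#' @return The serialized document as a single string (invisibly, when
#'   `file` is given).
#' @export
write_graph <- function(g, format = c("tsv", "obo", "graphml", "dot", "ntriples"),
                        file = NULL, label_iri_map = DEFAULT_LABEL_IRIS,
                        include_equivalences = TRUE) {
  format <- match.arg(format)
  ed <- sort_edges(g$edges)
  if (!include_equivalences) ed <- ed[ed$label != EQUIV_LABEL, , drop = FALSE]
  txt <- switch(format,
    tsv = {
      paste0(paste(c("source\tlabel\ttarget",
                     paste(ed$source, ed$label, ed$target, sep = "\t")),
                   collapse = "\n"), "\n")
    },
    obo = write_graph_obo(g, ed),
    dot = {
      lines <- c("digraph ontology {",
                 paste0("  \"", sort_ids(g$nodes), "\";"),
                 paste0("  \"", ed$source, "\" -> \"", ed$target,
                        "\" [label=\"", ed$label, "\"];"),
                 "}")
      paste0(paste(lines, collapse = "\n"), "\n")
    },
    graphml = {
      lines <- c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
        "  <key id=\"label\" for=\"edge\" attr.name=\"label\" attr.type=\"string\"/>",
        "  <graph id=\"G\" edgedefault=\"directed\">",
        paste0("    <node id=\"", xml_escape(sort_ids(g$nodes)), "\"/>"),
        paste0("    <edge source=\"", xml_escape(ed$source),
               "\" target=\"", xml_escape(ed$target),
               "\"><data key=\"label\">", xml_escape(ed$label),
               "</data></edge>"),
        "  </graph>",
        "</graphml>")
      paste0(paste(lines, collapse = "\n"), "\n")
    },
    ntriples = {
      pred <- vapply(ed$label, function(l) {
        if (l == IS_A) "http://www.w3.org/2000/01/rdf-schema#subClassOf"
        else if (l == EQUIV_LABEL) "http://www.w3.org/2002/07/owl#equivalentClass"
        else if (!is.na(label_iri_map[l])) unname(label_iri_map[l])
        else if (grepl("^[A-Za-z0-9]+:[A-Za-z0-9_.-]+$", l)) iri_from_curie(l)
        else stop("no IRI mapping for edge label: ", l)
      }, "")
      lines <- paste0("<", iri_from_curie(ed$source), "> <", pred, "> <",
                      iri_from_curie(ed$target), "> .")
      if (length(lines) == 0L) "" else paste0(paste(lines, collapse = "\n"), "\n")
    }
  )
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    return(invisible(txt))
  }
  txt
}

write_graph_obo <- function(g, ed) {
  lines <- c("format-version: 1.2", "")
  rel_labels <- sort_ids(setdiff(ed$label, c(IS_A, EQUIV_LABEL)))
  for (node in sort_ids(g$nodes)) {
    lines <- c(lines, "[Term]", paste0("id: ", node))
    sel <- ed[ed$source == node, , drop = FALSE]
    isa <- sort_ids(sel$target[sel$label == IS_A])
    lines <- c(lines, if (length(isa)) paste0("is_a: ", isa))
    eq <- sort_ids(c(sel$target[sel$label == EQUIV_LABEL],
                     ed$source[ed$label == EQUIV_LABEL & ed$target == node]))
    lines <- c(lines, if (length(eq)) paste0("equivalent_to: ", eq))
    rel <- sel[!(sel$label %in% c(IS_A, EQUIV_LABEL)), , drop = FALSE]
    if (nrow(rel)) {
      rel <- rel[order(rel$label, rel$target, method = "radix"), , drop = FALSE]
      lines <- c(lines, paste0("relationship: ", rel$label, " ", rel$target))
    }
    lines <- c(lines, "")
  }
  for (l in rel_labels) lines <- c(lines, "[Typedef]", paste0("id: ", l), "")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read a graph from a TSV edge list
#'
#' Inverse of the TSV writer: expects a `source<TAB>label<TAB>target`
#' header followed by one edge per line.
#'
#' @param text A string, character vector of lines, or path to a file.
#' @return An `ontology_graph` (mode recorded as `"unknown"`).
#' @export
read_graph_tsv <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || lines[1] != "source\tlabel\ttarget")
    stop("missing TSV header line")
  body <- lines[-1]
  if (!length(body))
    return(new_ontology_graph(character(0), edge_df(), "unknown", character(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("expected 3 columns at line ", bad[1] + 1L)
  m <- do.call(rbind, parts)
  ed <- edge_df(m[, 1], m[, 2], m[, 3])
  props <- sort_ids(setdiff(ed$label, c(IS_A, EQUIV_LABEL)))
  new_ontology_graph(c(ed$source, ed$target), ed, "unknown", props)
}

#' Serialize an ontology as an OBO flatfile
#'
#' Writes the OBO-expressible subset: named subclass axioms (`is_a:`),
#' existential subclass axioms with named fillers (`relationship:`), named
#' equivalences (`equivalent_to:`), equivalences between a named class and
#' an intersection of named classes and existential restrictions
#' (`intersection_of:`), sub-property axioms and transitivity declarations
#' (Typedef stanzas).  Axioms outside this subset raise an error.
#' [parse_obo()] applied to the output reconstructs the ontology.
#'
#' @param ont An [ontology()].
#' @param file Optional output path.
#' @return The document as a single string (invisibly, when `file` is
#'   given).
#' @export
write_obo_ontology <- function(ont, file = NULL) {
  term_lines <- lapply(ont$classes, function(x) character(0))
  names(term_lines) <- ont$classes
  type_lines <- lapply(ont$properties, function(x) character(0))
  names(type_lines) <- ont$properties
  add_term <- function(id, line) term_lines[[id]] <<- c(term_lines[[id]], line)

  for (ax in ont$axioms) {
    if (ax$type == "subclass" && is_named(ax$sub) && is_named(ax$sup)) {
      add_term(ax$sub$id, paste0("is_a: ", ax$sup$id))
    } else if (ax$type == "subclass" && is_named(ax$sub) &&
               ax$sup$kind == "some" && is_named(ax$sup$filler)) {
      add_term(ax$sub$id,
               paste0("relationship: ", ax$sup$prop, " ", ax$sup$filler$id))
    } else if (ax$type == "equiv" && length(ax$members) == 2L &&
               all(vapply(ax$members, is_named, TRUE))) {
      add_term(ax$members[[1]]$id,
               paste0("equivalent_to: ", ax$members[[2]]$id))
    } else if (ax$type == "equiv" && length(ax$members) == 2L &&
               is_named(ax$members[[1]]) && ax$members[[2]]$kind == "and") {
      parts <- vapply(ax$members[[2]]$args, function(a) {
        if (is_named(a)) a$id
        else if (a$kind == "some" && is_named(a$filler))
          paste(a$prop, a$filler$id)
        else stop("intersection member not expressible in OBO")
      }, "")
      term_lines[[ax$members[[1]]$id]] <-
        c(term_lines[[ax$members[[1]]$id]],
          paste0("intersection_of: ", sort(parts, method = "radix")))
    } else if (ax$type == "subprop") {
      type_lines[[ax$sub]] <- c(type_lines[[ax$sub]], paste0("is_a: ", ax$sup))
    } else if (ax$type == "transitive") {
      type_lines[[ax$prop]] <- c(type_lines[[ax$prop]], "is_transitive: true")
    } else {
      stop("axiom not expressible in OBO: ", axiom_key(ax))
    }
  }

  lines <- c("format-version: 1.2", "")
  for (id in sort_ids(ont$classes)) {
    lines <- c(lines, "[Term]", paste0("id: ", id),
               sort(term_lines[[id]], method = "radix"), "")
  }
  for (id in sort_ids(ont$properties)) {
    lines <- c(lines, "[Typedef]", paste0("id: ", id),
               sort(type_lines[[id]], method = "radix"), "")
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    return(invisible(txt))
  }
  txt
}
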