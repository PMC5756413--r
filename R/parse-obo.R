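# Reader for the OBO flatfile format (1.2/1.4 subset).

strip_obo_comment <- function(x) sub("\\s*!.*$", "", x)

#' Parse an OBO flatfile
#'
#' Reads `[Term]` and `[Typedef]` stanzas into an [ontology()].  `is_a:`
#' lines become named subclass axioms, `relationship: r Y` lines become
#' existential subclass axioms, complete `intersection_of` blocks become
#' equivalence axioms (term equivalent to the intersection of the listed
#' genus and relations), `equivalent_to:` lines become named equivalence
#' axioms.  Typedef `is_a:` lines become sub-property axioms and
#' `is_transitive: true` a transitivity declaration.  Terms marked
#' `is_obsolete: true` are skipped entirely.  Identifiers referenced but
#' never declared are auto-declared and recorded in `warnings`.
#'
#' @param text OBO document as a single string or character vector of lines.
#' @return An [ontology()].
#' @export
parse_obo <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)

  classes <- character(0); properties <- character(0)
  axioms <- list(); warnings <- character(0)
  declared <- character(0)

  # Collect stanzas as (type, first line number, named lines).
  stanza_type <- NA_character_; stanza_start <- 0L
  tags <- character(0); vals <- character(0); lnos <- integer(0)

  flush_term <- function() {
    if (is.na(stanza_type)) return()
    if (!any(tags == "id"))
      stop("malformed stanza at line ", stanza_start, ": missing id")
    id <- vals[tags == "id"][1]
    if (stanza_type == "Term") {
      if (any(tags == "is_obsolete" & grepl("^true", vals))) return()
      classes <<- c(classes, id)
      inter <- list()
      for (k in seq_along(tags)) {
        tag <- tags[k]; val <- strip_obo_comment(vals[k]); val <- trimws(val)
        if (tag == "is_a") {
          if (!nzchar(val)) stop("malformed is_a at line ", lnos[k])
          axioms[[length(axioms) + 1L]] <<- ax_subclass(id, val)
        } else if (tag == "relationship") {
          parts <- strsplit(val, "\\s+")[[1]]
          if (length(parts) < 2L)
            stop("malformed relationship at line ", lnos[k])
          axioms[[length(axioms) + 1L]] <<-
            ax_subclass(id, ce_some(parts[1], parts[2]))
          properties <<- c(properties, parts[1])
        } else if (tag == "intersection_of") {
          parts <- strsplit(val, "\\s+")[[1]]
          inter[[length(inter) + 1L]] <-
            if (length(parts) == 1L) ce_named(parts[1])
            else ce_some(parts[1], parts[2])
          if (length(parts) > 1L) properties <<- c(properties, parts[1])
        } else if (tag == "equivalent_to") {
          if (!nzchar(val)) stop("malformed equivalent_to at line ", lnos[k])
          axioms[[length(axioms) + 1L]] <<- ax_equiv(id, val)
        }
      }
      if (length(inter) == 1L) {
        warnings <<- c(warnings, paste0(
          "incomplete intersection_of block for ", id, " (1 element); skipped"))
      } else if (length(inter) >= 2L) {
        axioms[[length(axioms) + 1L]] <<-
          ax_equiv(ce_named(id), do.call(ce_and, inter))
      }
    } else if (stanza_type == "Typedef") {
      properties <<- c(properties, id)
      for (k in seq_along(tags)) {
        tag <- tags[k]; val <- trimws(strip_obo_comment(vals[k]))
        if (tag == "is_a") {
          axioms[[length(axioms) + 1L]] <<- ax_subprop(id, val)
        } else if (tag == "is_transitive" && grepl("^true", val)) {
          axioms[[length(axioms) + 1L]] <<- ax_transitive(id)
        }
      }
    }
    declared <<- c(declared, id)
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^\\[", line)) {
      flush_term()
      m <- regmatches(line, regexec("^\\[([A-Za-z]+)\\]\\s*$", line))[[1]]
      if (length(m) < 2L) stop("malformed stanza header at line ", i)
      stanza_type <- m[2]; stanza_start <- i
      tags <- character(0); vals <- character(0); lnos <- integer(0)
    } else if (!is.na(stanza_type) && nzchar(trimws(line))) {
      m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
      if (length(m) < 3L) stop("malformed line ", i, " in stanza: ", line)
      tags <- c(tags, m[2]); vals <- c(vals, m[3]); lnos <- c(lnos, i)
    }
  }
  flush_term()

  ont <- ontology(classes, properties, axioms)
  dangling <- setdiff(c(ont$classes, ont$properties), declared)
  dangling <- setdiff(dangling, c(OWL_THING, OWL_NOTHING))
  if (length(dangling))
    ont$warnings <- c(warnings, paste0("auto-declared undeclared identifier: ",
                                       sort_ids(dangling)))
  else ont$warnings <- warnings
  ont
}
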