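# Internal helpers shared across the package.

#' Reserved identifier of the top class
#' @format Character scalar.
#' @export
OWL_THING <- "owl:Thing"

#' Reserved identifier of the bottom class
#' @format Character scalar.
#' @export
OWL_NOTHING <- "owl:Nothing"

# Built-in edge labels; these are not object properties.
IS_A <- "is_a"
EQUIV_LABEL <- "equivalent_to"

OBO_PURL <- "http://purl.obolibrary.org/obo/"

# Locale-independent deterministic ordering (C collation via radix sort).
sort_ids <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(unique(as.character(x)), method = "radix")
}

# Fresh-name prefixes; excluded from all user-visible results.
is_fresh_id <- function(x) startsWith(x, ".N") | startsWith(x, ".Q")

#' Convert an IRI to a CURIE
#'
#' OBO-style PURLs (`http://purl.obolibrary.org/obo/GO_0016049`) become
#' CURIEs (`GO:0016049`); the OWL top and bottom IRIs map to their reserved
#' identifiers; anything else is returned unchanged.
#'
#' @param iri Character vector of IRIs.
#' @return Character vector of identifiers.
#' @export
curie_from_iri <- function(iri) {
  out <- iri
  out[iri == "http://www.w3.org/2002/07/owl#Thing"] <- OWL_THING
  out[iri == "http://www.w3.org/2002/07/owl#Nothing"] <- OWL_NOTHING
  obo <- startsWith(out, OBO_PURL)
  if (any(obo)) {
    local <- substring(out[obo], nchar(OBO_PURL) + 1L)
    out[obo] <- sub("_", ":", local)
  }
  out
}

#' Convert a CURIE to an IRI
#'
#' Inverse of [curie_from_iri()] on OBO-style identifiers: `GO:0016049`
#' becomes `http://purl.obolibrary.org/obo/GO_0016049`.  Identifiers without
#' a colon are placed directly under the OBO PURL namespace.
#'
#' @param id Character vector of identifiers.
#' @return Character vector of IRIs.
#' @export
iri_from_curie <- function(id) {
  out <- character(length(id))
  for (i in seq_along(id)) {
    x <- id[[i]]
    out[[i]] <-
      if (x == OWL_THING) "http://www.w3.org/2002/07/owl#Thing"
      else if (x == OWL_NOTHING) "http://www.w3.org/2002/07/owl#Nothing"
      else if (grepl("^[A-Za-z0-9]+:[A-Za-z0-9_.-]+$", x))
        paste0(OBO_PURL, sub(":", "_", x))
      else paste0(OBO_PURL, x)
  }
  out
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Canonical unordered pair key for entity pairs.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}
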