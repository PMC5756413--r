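# Annotation corpora, graph-based information content, and the simGIC and
# Resnik (best-match average) similarity measures.

#' Construct an annotation corpus
#'
#' @param direct Named list: entity id -> character vector of class ids
#'   (direct annotations).
#' @param propagated Optional named list of ancestor-closed annotation
#'   sets; filled in by [propagate_annotations()].
#' @param flagged Character vector of annotation classes that were absent
#'   from the graph during propagation.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(direct, propagated = NULL,
                              flagged = character(0)) {
  stopifnot(is.list(direct))
  direct <- direct[sort_ids(names(direct))]
  direct <- lapply(direct, sort_ids)
  structure(list(direct = direct, propagated = propagated,
                 flagged = flagged),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus> ", length(x$direct), " entities, ",
      length(unique(unlist(x$direct))), " distinct classes",
      if (!is.null(x$propagated)) " (propagated)" else "", "\n", sep = "")
  invisible(x)
}

#' Construct an interaction set
#'
#' Unordered entity pairs; self-pairs are dropped and each pair is stored
#' once with its members in lexicographic order.
#'
#' @param a,b Character vectors of entity ids (pair endpoints).
#' @param species Optional species tag.
#' @return An object of class `interaction_set`: data frame `pairs` with
#'   columns `a`, `b`, plus the `species` attribute.
#' @export
interaction_set <- function(a, b, species = NA_character_) {
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  df <- unique(data.frame(a = a2, b = b2, stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(pairs = df, species = species), class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("<interaction_set> ", nrow(x$pairs), " pairs",
      if (!is.na(x$species)) paste0(" (", x$species, ")") else "",
      "\n", sep = "")
  invisible(x)
}

gaf_fields <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines) & !startsWith(lines, "!")
  lnos <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 15L)
  if (length(bad))
    stop("GAF row with fewer than 15 columns at line ", lnos[bad[1]])
  list(rows = rows, lnos = lnos)
}

#' Parse a GAF annotation file
#'
#' Reads GAF 2.x tab-separated annotation lines (comments start with `!`)
#' into direct annotations: entity id from column 2, class id from column
#' 5.  Rows whose qualifier (column 4) contains `NOT` are dropped; rows
#' are kept only when their evidence code (column 7) is in
#' `evidence_whitelist` (an empty whitelist keeps all rows).
#'
#' @param text GAF content (string, lines, or file path).
#' @param evidence_whitelist Character vector of evidence codes to keep.
#' @return An [annotation_corpus()] with direct annotations only.
#' @export
parse_gaf <- function(text, evidence_whitelist = character(0)) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  parsed <- gaf_fields(text)
  ent <- character(0); cls <- character(0)
  for (f in parsed$rows) {
    qual <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    if ("NOT" %in% qual) next
    if (length(evidence_whitelist) && !(f[7] %in% evidence_whitelist)) next
    ent <- c(ent, f[2]); cls <- c(cls, f[5])
  }
  annotation_corpus(split(cls, ent))
}

#' Extract interaction pairs from GAF With/From fields
#'
#' Annotation rows carrying interaction-derived evidence codes (`IPI`,
#' physical; `IGI`, genetic) name the interaction partner in the With/From
#' field (column 8, `|`- or `,`-separated).  Each partner identifier
#' (database prefix stripped) is paired with the row's entity (column 2);
#' self-pairs are dropped and the codes are returned separately.
#'
#' @param text GAF content (string, lines, or file path).
#' @param codes Evidence codes to extract.
#' @return Named list of [interaction_set()] objects, one per code.
#' @export
extract_interactions_from_gaf <- function(text, codes = c("IGI", "IPI")) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  parsed <- gaf_fields(text)
  out <- lapply(codes, function(code) {
    a <- character(0); b <- character(0)
    for (k in seq_along(parsed$rows)) {
      f <- parsed$rows[[k]]
      if (f[7] != code) next
      if ("NOT" %in% strsplit(f[4], "|", fixed = TRUE)[[1]]) next
      partners <- trimws(strsplit(f[8], "[|,]")[[1]])
      partners <- partners[nzchar(partners)]
      if (!length(partners)) {
        warning("empty With/From on a ", code, " row at line ",
                parsed$lnos[k], "; row skipped", call. = FALSE)
        next
      }
      partners <- sub("^[A-Za-z0-9_.-]+:", "", partners)
      a <- c(a, rep(f[2], length(partners))); b <- c(b, partners)
    }
    interaction_set(a, b)
  })
  names(out) <- codes
  out
}

# Ancestor sets (reflexive) for every node of a graph, following every edge
# source -> target as a subclass link; equivalent_to edges connect both
# ways.  Returns a named list of sorted character vectors.
graph_ancestors <- function(g) {
  succ <- lapply(g$nodes, function(x) character(0))
  names(succ) <- g$nodes
  ed <- g$edges
  for (i in seq_len(nrow(ed))) {
    s <- ed$source[i]; t <- ed$target[i]
    succ[[s]] <- c(succ[[s]], t)
    if (ed$label[i] == EQUIV_LABEL) succ[[t]] <- c(succ[[t]], s)
  }
  anc <- new.env(parent = emptyenv())
  for (node in g$nodes) {
    if (!is.null(anc[[node]])) next
    # iterative DFS (graphs may contain equivalence cycles)
    stack <- node
    visited <- character(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v %in% visited) next
      visited <- c(visited, v)
      stack <- c(stack, setdiff(succ[[v]], visited))
    }
    anc[[node]] <- sort_ids(visited)
  }
  out <- lapply(g$nodes, function(x) anc[[x]])
  names(out) <- g$nodes
  out
}

#' Propagate annotations up a graph
#'
#' Treats every edge label as a subclass link (the standard rewriting that
#' makes property edges usable by subclass-based similarity measures):
#' `propagated(e)` is the union of the direct annotations of `e` and every
#' node reachable from them following edges source to target
#' (`equivalent_to` edges in both directions).  Annotation classes absent
#' from the graph are kept as themselves and recorded in `flagged`.
#'
#' @param corpus An [annotation_corpus()].
#' @param g An `ontology_graph`.
#' @return The corpus with `propagated` filled in.
#' @export
propagate_annotations <- function(corpus, g) {
  anc <- graph_ancestors(g)
  flagged <- character(0)
  propagated <- lapply(corpus$direct, function(cls) {
    known <- intersect(cls, g$nodes)
    unknown <- setdiff(cls, g$nodes)
    if (length(unknown)) flagged <<- c(flagged, unknown)
    sort_ids(c(unknown, unlist(anc[known], use.names = FALSE)))
  })
  corpus$propagated <- propagated
  corpus$flagged <- sort_ids(flagged)
  corpus
}

#' Corpus information content
#'
#' `ic(c) = -log2(freq(c) / N)` where `freq(c)` is the number of entities
#' whose propagated annotation set contains `c` and `N` the number of
#' annotated entities.  Classes annotated to every entity (such as the
#' root) get 0 bits; classes with zero frequency are absent from the map.
#'
#' @param corpus A propagated [annotation_corpus()].
#' @param g Unused placeholder kept for interface symmetry with the
#'   similarity functions; may be `NULL`.
#' @return Named numeric vector of information contents (bits).
#' @export
information_content <- function(corpus, g = NULL) {
  if (is.null(corpus$propagated))
    stop("corpus must be propagated first (see propagate_annotations)")
  if (length(corpus$propagated) == 0L) stop("empty corpus")
  n <- length(corpus$propagated)
  freq <- table(unlist(corpus$propagated, use.names = FALSE))
  ic <- -log2(as.numeric(freq) / n)
  names(ic) <- names(freq)
  ic[sort_ids(names(ic))]
}

entity_sets <- function(corpus, e1, e2, slot) {
  sets <- corpus[[slot]]
  for (e in c(e1, e2)) if (is.null(sets[[e]])) stop("unknown entity: ", e)
  list(sets[[e1]], sets[[e2]])
}

#' simGIC similarity between two entities
#'
#' Sum of information contents over the intersection of the two propagated
#' annotation sets divided by the sum over their union; 0 when the union
#' carries no information.
#'
#' @param e1,e2 Entity identifiers.
#' @param corpus A propagated [annotation_corpus()].
#' @param icmap Named numeric vector from [information_content()].
#' @return A number in `[0, 1]`.
#' @export
sim_gic <- function(e1, e2, corpus, icmap) {
  s <- entity_sets(corpus, e1, e2, "propagated")
  a <- intersect(s[[1]], names(icmap)); b <- intersect(s[[2]], names(icmap))
  den <- sum(icmap[union(a, b)])
  if (den == 0) return(0)
  sum(icmap[intersect(a, b)]) / den
}

#' Resnik similarity with best-match averaging
#'
#' The pairwise similarity of two classes is the information content of
#' their most informative common ancestor in the graph (all edge labels
#' treated as subclass).  Entity-level similarity combines the pairwise
#' values over the two direct annotation sets by best-match average: the
#' mean of each class's best match in the other set, averaged over both
#' directions.
#'
#' @inheritParams sim_gic
#' @param g The `ontology_graph` supplying the ancestor relation.
#' @param on_propagated Use propagated instead of direct annotation sets.
#' @return A non-negative number (bits).
#' @export
resnik_bma <- function(e1, e2, corpus, icmap, g, on_propagated = FALSE) {
  slot <- if (on_propagated) "propagated" else "direct"
  s <- entity_sets(corpus, e1, e2, slot)
  anc <- graph_ancestors(g)
  anc_of <- function(c0) if (is.null(anc[[c0]])) c0 else anc[[c0]]
  pair_sim <- function(c1, c2) {
    common <- intersect(intersect(anc_of(c1), anc_of(c2)), names(icmap))
    if (!length(common)) 0 else max(icmap[common])
  }
  m <- outer(s[[1]], s[[2]], Vectorize(pair_sim))
  if (length(m) == 0L) return(0)
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

#' All pairwise similarities of a corpus
#'
#' Computes the chosen similarity for every unordered pair of annotated
#' entities.  simGIC is evaluated with a vectorized set-weight
#' formulation; Resnik best-match average loops over pairs and is intended
#' for small corpora.
#'
#' @param corpus An [annotation_corpus()] (propagated, or it will be
#'   propagated against `g`).
#' @param g An `ontology_graph`.
#' @param measure `"simgic"` or `"resnik"`.
#' @return Named numeric vector of scores keyed by
#'   `paste(min, max, sep = "\t")` over entity pairs.
#' @export
pairwise_similarity <- function(corpus, g, measure = c("simgic", "resnik")) {
  measure <- match.arg(measure)
  if (is.null(corpus$propagated)) corpus <- propagate_annotations(corpus, g)
  icmap <- information_content(corpus)
  ents <- names(corpus$propagated)
  if (length(ents) < 2L) stop("need at least two annotated entities")
  pairs <- utils::combn(ents, 2L)
  keys <- pair_key(pairs[1, ], pairs[2, ])
  if (measure == "simgic") {
    cls <- names(icmap)
    M <- matrix(0, length(ents), length(cls), dimnames = list(ents, cls))
    for (e in ents) {
      hit <- intersect(corpus$propagated[[e]], cls)
      M[e, hit] <- 1
    }
    W <- M * rep(icmap, each = length(ents))
    inter <- W %*% t(M)
    tot <- rowSums(W)
    uni <- outer(tot, tot, "+") - inter
    sim <- ifelse(uni > 0, inter / uni, 0)
    scores <- sim[cbind(pairs[1, ], pairs[2, ])]
  } else {
    scores <- vapply(seq_len(ncol(pairs)), function(k)
      resnik_bma(pairs[1, k], pairs[2, k], corpus, icmap, g), 0)
  }
  names(scores) <- keys
  scores
}
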