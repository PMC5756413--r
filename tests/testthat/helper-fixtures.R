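# Shared helpers for the test suite.

fixture <- function(name) {
  path <- system.file("extdata", name, package = "ontograph")
  stopifnot(nzchar(path))
  path
}

read_fixture_ontology <- function(name) {
  if (grepl("\\.obo$", name)) parse_obo(readLines(fixture(name)))
  else parse_ofn(readLines(fixture(name)))
}

# Edge data frame as a sorted key vector, for set comparisons.
edge_keys <- function(ed) {
  sort(paste(ed$source, ed$label, ed$target, sep = " / "), method = "radix")
}

axiom_keys <- function(ont) {
  sort(vapply(ont$axioms, ontograph:::axiom_key, ""), method = "radix")
}

# Exhaustive-enumeration AUC: P(pos > neg) + 0.5 P(pos == neg).
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Textbook DAG transitive reduction by boolean matrices: drop an edge when
# a two-or-more-step path connects its endpoints.
brute_isa_reduction <- function(ed, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(ed$source, ed$target)] <- TRUE
  C <- A
  repeat {
    C2 <- C | ((C %*% C) > 0)
    if (identical(C2, C)) break
    C <- C2
  }
  keep <- A & !((A %*% C) > 0)
  w <- which(keep, arr.ind = TRUE)
  out <- data.frame(source = nodes[w[, 1]], label = "is_a",
                    target = nodes[w[, 2]], stringsAsFactors = FALSE)
  out[order(out$source, out$target, method = "radix"), , drop = FALSE]
}

# The two-class retarget fixture: Z under an existential whose filler has a
# more specific subclass.
most_specific_fixture <- function() {
  ontology(axioms = list(
    ax_subclass("Y", "X"),
    ax_subclass("Z", ce_some("p", "Y"))))
}
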