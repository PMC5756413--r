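# ROC evaluation of similarity-based interaction prediction.

# AUC by the rank-sum identity with midranks for ties.
auc_from_scores <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  list(auc = u / (np * nn), u = u)
}

#' ROC analysis of pairwise similarity scores
#'
#' Positives are the given interaction pairs; negatives are all other
#' unordered pairs over the entity universe.  The area under the ROC curve
#' is computed through the rank-sum identity (midranks for ties), together
#' with the Mann-Whitney U statistic and a two-sided normal-approximation
#' p-value (tie- and continuity-corrected) for the rank-sum test.
#'
#' @param similarities Named numeric vector of scores keyed by
#'   `paste(min, max, sep = "\t")` (as produced by
#'   [pairwise_similarity()]); must cover every pair over `universe`.
#' @param positives An [interaction_set()].
#' @param universe Character vector of entity ids defining the negative
#'   pair universe.
#' @return An object of class `roc_result`: `auc`, `n_pos`, `n_neg`,
#'   `u_statistic`, `p_value`.
#' @export
roc_auc <- function(similarities, positives, universe) {
  universe <- sort_ids(universe)
  if (length(universe) < 2L) stop("universe must contain at least 2 entities")
  allp <- utils::combn(universe, 2L)
  keys <- pair_key(allp[1, ], allp[2, ])
  missing <- setdiff(keys, names(similarities))
  if (length(missing))
    stop("missing similarity scores for ", length(missing), " pair(s)")
  pk <- pair_key(positives$pairs$a, positives$pairs$b)
  pk <- intersect(pk, keys)
  is_pos <- keys %in% pk
  if (!any(is_pos)) stop("zero positive pairs in the universe")
  if (all(is_pos)) stop("zero negative pairs in the universe")
  sc <- unname(similarities[keys])
  res <- auc_from_scores(sc[is_pos], sc[!is_pos])
  p <- tryCatch(
    stats::wilcox.test(sc[is_pos], sc[!is_pos], exact = FALSE,
                       correct = TRUE)$p.value,
    error = function(e) NA_real_)
  if (is.na(p) || is.nan(p)) p <- 1
  structure(list(auc = res$auc, n_pos = sum(is_pos), n_neg = sum(!is_pos),
                 u_statistic = res$u, p_value = min(max(p, 0), 1)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d pos / %d neg), U = %.1f, p = %.3g\n",
              x$auc, x$n_pos, x$n_neg, x$u_statistic, x$p_value))
  invisible(x)
}

#' Compare interaction-prediction performance of two graphs
#'
#' Scores every entity pair of the corpus under both graphs with the
#' chosen similarity measure, computes each graph's ROC AUC against the
#' positive interaction set, and tests the AUC difference with a seeded
#' permutation test: the positive/negative labels are permuted jointly
#' over the pair universe `n_perm` times and the absolute AUC difference
#' recompared.  A Bonferroni-adjusted p-value is reported when the
#' comparison is one of `n_comparisons` planned comparisons.
#'
#' @param g1,g2 `ontology_graph` objects over the same ontology.
#' @param corpus An [annotation_corpus()] (direct annotations).
#' @param positives An [interaction_set()].
#' @param measure `"simgic"` or `"resnik"`.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation draw.
#' @param n_comparisons Number of planned comparisons for the Bonferroni
#'   adjustment.
#' @return An object of class `graph_comparison`: `auc1`, `auc2`,
#'   `difference`, `p_permutation`, `p_adjusted`, `roc1`, `roc2`.
#' @export
compare_graph_performance <- function(g1, g2, corpus, positives,
                                      measure = c("simgic", "resnik"),
                                      n_perm = 1000L, seed = 1L,
                                      n_comparisons = 1L) {
  measure <- match.arg(measure)
  s1 <- pairwise_similarity(corpus, g1, measure)
  s2 <- pairwise_similarity(corpus, g2, measure)
  universe <- names(corpus$direct)
  roc1 <- roc_auc(s1, positives, universe)
  roc2 <- roc_auc(s2, positives, universe)
  d_obs <- roc1$auc - roc2$auc

  allp <- utils::combn(sort_ids(universe), 2L)
  keys <- pair_key(allp[1, ], allp[2, ])
  pk <- pair_key(positives$pairs$a, positives$pairs$b)
  is_pos <- keys %in% pk
  r1 <- rank(unname(s1[keys])); r2 <- rank(unname(s2[keys]))
  np <- sum(is_pos); nn <- sum(!is_pos)
  auc_of <- function(r, lab) {
    (sum(r[lab]) - np * (np + 1) / 2) / (np * nn)
  }
  d_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    lab <- sample(is_pos)
    auc_of(r1, lab) - auc_of(r2, lab)
  }, 0))
  p_perm <- (1 + sum(abs(d_perm) >= abs(d_obs) - 1e-12)) / (n_perm + 1)
  structure(list(auc1 = roc1$auc, auc2 = roc2$auc, difference = d_obs,
                 p_permutation = p_perm,
                 p_adjusted = min(1, p_perm * n_comparisons),
                 measure = measure, n_perm = n_perm,
                 roc1 = roc1, roc2 = roc2),
            class = "graph_comparison")
}

#' @export
print.graph_comparison <- function(x, ...) {
  cat(sprintf(paste0("<graph_comparison> %s: AUC1 %.4f vs AUC2 %.4f ",
                     "(diff %+.4f), permutation p = %.3g (adjusted %.3g)\n"),
              x$measure, x$auc1, x$auc2, x$difference,
              x$p_permutation, x$p_adjusted))
  invisible(x)
}
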