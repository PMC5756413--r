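---
title: "Inferring labeled graphs from OWL ontologies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring labeled graphs from OWL ontologies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontograph)
```

## The problem

Graph-based analysis methods — semantic similarity, enrichment, most
visualization — consume ontologies as labeled directed graphs over named
classes.  Axiom-based ontologies do not come in that shape: a relation such
as *part-of* may only be implied by an equivalence definition, a property
hierarchy, a union on the subclass side, or a chain of such axioms.  This
package converts an ontology into a labeled multigraph whose edges are
backed by entailment, so that the graph captures the deductive closure of
the axioms rather than their surface syntax.

## Supported logic and the reasoner

The supported fragment is EL+ : named classes, conjunction, existential
restriction, equivalence, role hierarchies (`r ⊑ s`) and transitivity
(encoded as `r ∘ r ⊑ r` only; general role chains are rejected).  Unions
are additionally allowed as the *whole* subclass side of an axiom and are
compiled away by splitting (`A ⊔ B ⊑ C` becomes `A ⊑ C`, `B ⊑ C`); unions
anywhere else are a validation error.  This fragment covers what the
conversion algorithm exploits and what EL reasoners classify in
polynomial time; nothing in the pipeline requires negation, universal
restrictions or cardinalities, which are out of scope.

`normalize_ontology()` rewrites every axiom into the five EL normal forms,
introducing fresh names (prefix `.N`) as *full definitions* of complex
sub-expressions, memoized per expression so shared sub-expressions get one
name.  Full definitions (both directions) are slightly more axioms than the
minimal textbook normalization but make soundness immediate and keep fresh
names meaningful.  `saturate()` then applies the completion rules —
initialization, atomic subsumption, conjunction, existential introduction,
existential-filler propagation, role hierarchy, transitivity, bottom
propagation along links — to a fixpoint, over logical matrices indexed by
class.  Fresh names never leak into user-visible results.

Existential queries ("which named `Z` satisfy `Z ⊑ ∃o.X`?") introduce a
fresh query name defined as the restriction and read its subsumees off the
saturation.  One conversion run batches *all* (property, target) queries
into a single saturation; without batching the conversion would saturate
once per class and property.

A syntactic ("told") mode mirrors structural reasoners: the taxonomy uses
only asserted subclass/equivalence axioms between named classes, and a
told existential query returns the classes asserted under an expression
syntactically equal to `∃o.X`.  Whether such a pattern should also be
extracted from inside an asserted conjunction (e.g. the differentia of a
genus-differentia definition) is a dialect question with no canonical
answer; we extract top-level conjuncts, which makes definitions like
`X ≡ G ⊓ ∃p.W` visible to both modes and keeps the told answers a subset
of the entailed ones.

## The conversion algorithm

For each requested property `o`, the candidate sources of a target `X` are
the entailed (or told) subclasses of `∃o.X`.  An edge `Z →(o)→ X` is
emitted iff `Z` is a candidate of `X` and of no *direct* subclass `Y` of
`X` — the most-specific-successor filter.  Filtering against direct
subclasses only is an optimization: under entailment, candidacy is
monotone along the taxonomy (`Z ⊑ ∃o.Y` and `Y ⊑ Y′` imply `Z ⊑ ∃o.Y′`),
so if any subclass of `X` is a candidate then some direct subclass is.
The test suite checks this equivalence edge-for-edge against an oracle
that filters against *all* subclasses, in both modes.

Design choices that the definition leaves open, resolved as follows:

* **Equivalence cliques** are collapsed to their lexicographically
  smallest member for all path computations; `equivalent_to` edges between
  clique members are emitted in the output.  Candidate sets are computed
  once per representative (member-level patterns are unioned over the
  clique), not per member.
* **Reflexive relational edges** (`Z →(o)→ Z`) and edges targeting the top
  class are suppressed as uninformative.  Reflexive *candidates* still
  participate in the most-specific filter — suppression applies to emitted
  edges only, which keeps the direct-subclass optimization exact.
* The most-specific filter is applied in the syntactic mode too (the told
  taxonomy supplies the direct subclasses); `specific_filter = FALSE`
  disables it in either mode.
* In syntactic mode, sub-property edges are materialized after edge
  generation: every edge `(X, o1, Y)` with `o1 ⊑* o2` and `o2` requested
  yields `(X, o2, Y)`.  In semantic mode this is a no-op because
  entailment already produces the super-property edges.

## Transitive reduction and its closure

The reduction operates on the final multigraph, after propagation, with
equivalence cliques already collapsed.  Labels compose along a path by
three rules: `is_a` is the identity on either side of any edge; two
relational edges compose only under a common *transitive* property that
both labels reach in the told hierarchy; and any relational label entails
every told super-property.  `graph_closure()` is the fixpoint of these
rules; `transitive_reduction()` removes, in lexicographic edge order, every
edge derivable from the remaining edges, so `closure(reduced) ==
closure(original)` exactly and the result is minimal (removing any further
edge strictly shrinks the closure).  One deliberate consequence of
defining removal by derivability: a parallel sub-property edge alone can
justify removing its super-property twin (`(a, q, b)` with `q ⊑ p` makes
`(a, p, b)` redundant), since the closure regenerates the super-property
triple by lifting.  Defining removal instead by multi-edge paths only
would leave such edges in place and break minimality with respect to the
closure, so we chose the closure-consistent definition.  Greedy removal in
a fixed lexicographic order makes the output deterministic; on a pure
`is_a` graph the procedure coincides with the unique textbook DAG
transitive reduction.

Determinism is a package-wide invariant: all sets are iterated in C-locale
lexicographic order, all writers sort their output, and conversion output
is byte-identical across runs and across input axiom orderings.

## Similarity and ROC evaluation

Before computing similarity, every edge label is rewritten as a subclass
link, the standard trick that lets subclass-based measures exploit
relational edges; `propagate_annotations()` closes each entity's
annotation set under this ancestor relation (equivalence edges act in both
directions).  Annotation classes absent from the graph are kept as
themselves and flagged.

Information content is corpus-based: `IC(c) = −log₂(freq(c)/N)` with
`freq` counted over propagated sets.  Base 2 (bits) is a convention;
ROC results are invariant to the base, absolute similarity values are not.
simGIC operates on propagated sets (the standard choice); Resnik
similarity takes the maximum IC over common ancestors and is combined by
best-match averaging over *direct* annotation sets, the conventional BMA
formulation (`on_propagated = TRUE` switches to propagated sets).

`roc_auc()` treats given interaction pairs as positives and **all other
unordered pairs over the annotated entities of the corpus** as negatives
(the negative universe is deliberately per-dataset).  The AUC comes from
the rank-sum identity with midranks; the U statistic's two-sided p-value
uses the normal approximation with tie and continuity correction
(`stats::wilcox.test`).  Degenerate inputs — no positives, no negatives,
all-tied scores with zero variance — are an error, an error, and `p = 1`
respectively.  For comparing two graphs on the same pairs, a single
rank-sum test is not well defined (the two AUCs share the same pairs), so
`compare_graph_performance()` reports a seeded permutation test: the
positive/negative labels are permuted jointly `n_perm` times (default
1000) and the absolute AUC difference recompared, with an optional
Bonferroni adjustment for planned multiple comparisons.

## What the generators emulate — and what they do not

`random_ontology()` draws index-monotone taxonomies (acyclic by
construction), existential assertions, genus-differentia equivalence
definitions, property hierarchies and transitive properties, all
reproducible from a seed.  Two deliberate choices: equivalence-induced
cycles are exercised through dedicated fixtures rather than the random
taxonomy, keeping clique handling covered without uncontrolled cyclic
tangles; and each (class, property) pair asserts at most one existential
restriction, the usual shape of OBO relationship and definition lines.
The latter matters for the told mode: with several same-property
assertions from one class to taxonomically related targets, the
direct-subclass and all-subclass filters can legitimately disagree under
told (non-monotone) candidacy, so the generator stays within the regime
where the optimization is exact in both modes.

`scenario_a()` is a desk-scale analogue of evaluating reasoner-built
versus syntactically-built Gene Ontology graphs: ~54 classes (a root, 35
process classes, 8 anchor "whole" classes, 10 defined classes), a
transitive `part_of` with told sub-property `directly_part_of`, 200
annotated entities with 2–4 direct annotations each.  Sixty percent of the
process classes reach their anchor only through the sub-property, so a
syntactic `part_of` conversion misses those links while the reasoner
recovers them — every seed yields strictly more semantic `part_of` edges.
Interacting pairs are sampled with probability
`plogis(−4 + signal · z)`, where `z` is the standardized count of shared
propagated annotation classes under the semantic graph: the
`interaction_signal` knob (default 5) is the log-odds increase per
standard deviation of shared-annotation count (standardizing keeps the
logistic in its informative range regardless of corpus density), and
`signal = 0` gives a label-free null whose AUC concentrates at 0.5.

What the generator does **not** emulate: real GO-scale ontologies (tens of
thousands of classes), annotation biases (shallow-annotation clustering,
evidence-code structure), literature-driven interaction ascertainment, or
cross-species transfer.  Passing tests therefore demonstrate correctness
of the machinery and the *direction* of the semantic-vs-syntactic effect
under controlled conditions, not effect sizes on real corpora.

## Problem sizes and tolerances

The property suites run 200 seeded ontologies of up to 30 classes/60
axioms against the naive reasoner oracle, 200 of up to 25 classes against
the all-subclass conversion oracle in both modes, 200 random multigraphs
for closure preservation and minimality, and 20 scenario seeds (200
entities, 19 900 pairs each) for the ROC comparison — sizes chosen so the
oracles (intentionally exponential-ish) stay comfortable while covering
the combinatorics.  Hand-computed similarity values are asserted to
1e−12; AUC equalities to exhaustive enumeration likewise.  The null-AUC
band [0.45, 0.55] over 20 seeds reflects sampling noise at ~400 positive
pairs per seed.

## Known limitations

* Only the `∃o.X` pattern generates relational edges; axioms whose
  relational content is not expressible that way contribute nothing.
* Transitivity is the only supported role composition; `r ∘ s ⊑ t` is
  rejected.
* The told mode's conjunct extraction is a dialect choice (see above); the
  told taxonomy ignores named classes related only through complex
  equivalences.
* `resnik_bma()` recomputes the ancestor table per call and loops over
  annotation pairs; it is intended for small corpora, while the simGIC
  path is vectorized.
* OBO parsing covers the logical subset ([Term]/[Typedef] stanzas, `is_a`,
  `relationship`, `intersection_of`, `equivalent_to`, `is_transitive`,
  obsolete skipping); annotation-level tags are ignored.  Obsolete terms
  carry no logical content and are excluded from the class set.
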