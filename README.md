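# ontograph

`ontograph` turns OWL ontologies into labeled multigraphs by *deductive*
inference, and evaluates what those graphs buy you in ontology-based data
analysis.

Biomedical ontologies such as the Gene Ontology were historically
distributed as directed acyclic graphs — `is_a` and `part_of` edges between
named classes — and a large ecosystem of methods (semantic similarity,
enrichment analysis, visualization) consumes exactly that structure.  Modern
ontologies, however, are sets of OWL axioms: relations are often stated
through complex class expressions (`X EquivalentTo: G and (part_of some
W)`, unions, property hierarchies) that no longer correspond to any single
edge.  A purely syntactic scan of the axioms misses every relation that is
implied but not asserted.

`ontograph` closes that gap.  For each requested object property *o* and
candidate target *X*, it asks an automated reasoner which named classes *Z*
are entailed to satisfy *Z ⊑ ∃o.X*, and draws an edge *Z* →(o)→ *X* only
when *X* is the **most specific** such target (no direct subclass *Y* of
*X* also satisfies *Z ⊑ ∃o.Y*).  The backbone of the graph is the inferred
taxonomy (direct `is_a` edges on equivalence-class representatives plus
`equivalent_to` edges inside cliques).  An optional **transitive
reduction** removes every edge derivable from the remaining ones under
label composition (`is_a` absorbs on either side of a relational edge;
equal labels compose when the property is transitive; labels lift along the
told property hierarchy), preserving the reachability closure exactly.

The reasoner is a built-in EL+ engine: structural normalization to the five
EL normal forms followed by completion-rule saturation (conjunction,
existential propagation, role hierarchy, transitivity `r ∘ r ⊑ r`).  A
purely syntactic ("told") mode is provided for comparison, mirroring
structural reasoners.

The evaluation layer implements graph-based semantic similarity —
**simGIC**, `sim(e₁,e₂) = Σ_{c ∈ P₁∩P₂} IC(c) / Σ_{c ∈ P₁∪P₂} IC(c)` over
ancestor-closed annotation sets with `IC(c) = −log₂(freq(c)/N)`, and
**Resnik** similarity (information content of the most informative common
ancestor) combined by best-match averaging — plus ROC analysis of
interaction prediction: positives are known interacting pairs, negatives
all other pairs, and the AUC is computed through the Mann–Whitney rank-sum
identity with midranks for ties.

## Worked example

The shipped fixture `subproperty_chain.obo` contains a three-class chain
`a →(q)→ b →(q)→ c` where `q` is transitive and a sub-property of `p`.
Nothing is asserted about `p` directly:

```r
library(ontograph)
obo <- system.file("extdata", "subproperty_chain.obo", package = "ontograph")
ont <- parse_obo(readLines(obo))

g <- build_graph(ont, c("p", "q"), mode = "semantic")
cat(write_graph(g, "tsv"))
#> source	label	target
#> T:a	p	T:b
#> T:a	p	T:c
#> T:a	q	T:b
#> T:a	q	T:c
#> T:b	p	T:c
#> T:b	q	T:c
```

The reasoner recovers all six implied edges: the asserted `q` chain, its
transitive composition `a →(q)→ c`, and every `p` edge implied by `q ⊑ p`.
A syntactic conversion restricted to `p` finds none of them
(`build_graph(ont, "p", mode = "syntactic")` has 0 edges).  Transitive
reduction keeps only the two edges from which everything else is
derivable:

```r
gr <- build_graph(ont, c("p", "q"), mode = "semantic", reduce = TRUE)
cat(write_graph(gr, "tsv"))
#> source	label	target
#> T:a	q	T:b
#> T:b	q	T:c
```

Graphs can be written as TSV, OBO, GraphML, GraphViz DOT or N-Triples
(`write_graph`), and the same pipeline is available from a shell through
`inst/scripts/ontograph convert` / `evaluate`.

For evaluation, `scenario_a()` generates a seeded ontology in which part
of the `part_of` content is reachable only through deduction, an annotated
entity corpus, and interaction pairs enriched for shared annotations;
`pairwise_similarity()`, `roc_auc()` and `compare_graph_performance()`
then quantify how much the reasoner-built graph improves interaction
prediction over the syntactic one.

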