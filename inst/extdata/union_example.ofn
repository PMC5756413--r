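Ontology(<http://example.org/union-example>
Declaration(Class(:A))
Declaration(Class(:B))
Declaration(Class(:C))
Declaration(ObjectProperty(:R))
SubClassOf(ObjectUnionOf(:A :B) ObjectSomeValuesFrom(:R :C))
)
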