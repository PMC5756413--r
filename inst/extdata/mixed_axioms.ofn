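Ontology(<http://example.org/mixed-axioms>
Declaration(Class(:X))
Declaration(Class(:G))
Declaration(Class(:W))
Declaration(Class(:A))
Declaration(Class(:B))
Declaration(Class(:C))
Declaration(ObjectProperty(:p))
Declaration(ObjectProperty(:q))
SubClassOf(:A :B)
SubClassOf(:A ObjectSomeValuesFrom(:q :C))
EquivalentClasses(:X ObjectIntersectionOf(:G ObjectSomeValuesFrom(:p :W)))
SubClassOf(ObjectUnionOf(:B :C) :G)
SubObjectPropertyOf(:q :p)
TransitiveObjectProperty(:p)
)
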