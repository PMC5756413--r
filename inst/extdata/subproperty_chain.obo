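format-version: 1.2
ontology: subproperty-chain-example

[Term]
id: T:a
relationship: q T:b

[Term]
id: T:b
relationship: q T:c

[Term]
id: T:c

[Typedef]
id: p
is_transitive: true

[Typedef]
id: q
is_a: p
is_transitive: true
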