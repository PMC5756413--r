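format-version: 1.2
ontology: toy-similarity

[Term]
id: R:0001
name: root process

[Term]
id: A:0001
name: branch one
is_a: R:0001

[Term]
id: A:0002
name: branch two
is_a: R:0001

[Term]
id: B:0001
name: leaf one
is_a: A:0001

[Term]
id: B:0002
name: leaf two
is_a: A:0001

[Term]
id: B:0003
name: leaf three
is_a: A:0002

[Term]
id: B:0004
name: leaf four
is_a: A:0002
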