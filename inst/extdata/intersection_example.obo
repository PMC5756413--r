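format-version: 1.2
ontology: intersection-example

[Term]
id: X:0001
name: defined class
intersection_of: G:0001
intersection_of: part_of W:0001

[Term]
id: G:0001
name: genus

[Term]
id: W:0001
name: whole

[Typedef]
id: part_of
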