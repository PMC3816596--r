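format-version: 1.4
ontology: mini-clfbbt

[Term]
id: CL:0000000
name: cell

[Term]
id: FBbt:00000001
name: organism

[Term]
id: FBbt:00100313
name: multicellular structure
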