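format-version: 1.4
ontology: fly-stages

[Term]
id: FBdv:00005289
name: embryonic stage

[Term]
id: FBdv:00005336
name: larval stage
relationship: immediately_preceded_by FBdv:00005289

[Term]
id: FBdv:00005342
name: pupal stage
relationship: immediately_preceded_by FBdv:00005336

[Term]
id: FBdv:00007026
name: mature adult stage
relationship: immediately_preceded_by FBdv:00005342

[Typedef]
id: immediately_preceded_by
name: immediately_preceded_by
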