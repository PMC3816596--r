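format-version: 1.4
subsetdef: eq_pattern_tags "Custom stanza tags equivalent_union_of and necessary_intersection_of carry pattern definitions; third-party parsers may ignore them"
ontology: mini-dpo

[Term]
id: FBcv:0000001
name: phenotype
def: "A quality of some anatomical structure, process or behavior that differs from wild-type." [FBC:fixture]
intersection_of: PATO:0000001
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000362
name: increased cell number
is_a: FBcv:0000001
intersection_of: PATO:0002002
intersection_of: inheres_in FBbt:00100313
intersection_of: towards CL:0000000

[Term]
id: FBcv:0000363
name: increased cell size
is_a: FBcv:0000001
intersection_of: PATO:0000586
intersection_of: inheres_in CL:0000000

[Term]
id: FBcv:0000387
name: behavior defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0007610
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000394
name: circadian rhythm defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0007623
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000408
name: stress response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0006950
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000415
name: jumping defective
def: "Flies fail to jump in a standard assay, with no controls discounting physical explanations such as defective legs; neutral about whether the defect is behavioral." [FBC:fixture]
necessary_intersection_of: PATO:0000001
necessary_intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000423
name: DNA repair defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0006281
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000425
name: cell death defective
equivalent_union_of: PATTERN:0000001 PATTERN:0000002

[Term]
id: FBcv:0000439
name: radiation resistant
def: "A phenotype that is a decreased sensitivity to radiation." [FBC:fixture]
is_a: FBcv:0000001
intersection_of: PATO:0001552
intersection_of: inheres_in GO:0009314

[Term]
id: FBcv:0000679
name: circadian behavior defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0048512
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000683
name: temperature response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0009266
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000684
name: cold stress response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0009409
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000686
name: heat stress response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0009408
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000687
name: oxidative stress response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0006979
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000688
name: DNA damage response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0006974
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000689
name: defense response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0006952
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000690
name: wound response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0009611
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000691
name: wound healing defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0042060
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000692
name: sensory perception defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0007600
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000693
name: hearing defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0007605
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000694
name: jump response defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0007630
intersection_of: qualifier PATO:0000460

[Term]
id: FBcv:0000695
name: apoptosis defective
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0006915
intersection_of: qualifier PATO:0000460

[Term]
id: PATTERN:0000001
is_anonymous: true
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0012501
intersection_of: qualifier PATO:0000460

[Term]
id: PATTERN:0000002
is_anonymous: true
intersection_of: PATO:0000001
intersection_of: inheres_in GO:0043067
intersection_of: qualifier PATO:0000460
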