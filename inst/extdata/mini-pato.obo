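format-version: 1.4
ontology: mini-pato

[Term]
id: PATO:0000001
name: quality
namespace: quality

[Term]
id: PATO:0000117
name: size
namespace: quality
is_a: PATO:0000001

[Term]
id: PATO:0000460
name: abnormal
namespace: quality
is_a: PATO:0000001

[Term]
id: PATO:0000586
name: increased size
namespace: quality
is_a: PATO:0000117

[Term]
id: PATO:0001236
name: process quality
namespace: quality
is_a: PATO:0000001

[Term]
id: PATO:0001457
name: sensitivity of a process
namespace: quality
is_a: PATO:0001236

[Term]
id: PATO:0001552
name: decreased sensitivity of a process
namespace: quality
is_a: PATO:0001457

[Term]
id: PATO:0002002
name: has extra parts of type
namespace: quality
is_a: PATO:0000001
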