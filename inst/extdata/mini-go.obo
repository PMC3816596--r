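format-version: 1.4
ontology: mini-go

[Term]
id: GO:0006281
name: DNA repair
namespace: biological_process
def: "The process of restoring DNA after damage." [GOC:fixture]
is_a: GO:0006974

[Term]
id: GO:0006915
name: apoptotic process
namespace: biological_process
is_a: GO:0012501

[Term]
id: GO:0006950
name: response to stress
namespace: biological_process
def: "Any process that results in a change in state or activity of a cell or an organism (in terms of movement, secretion, enzyme production, gene expression, etc.) as a result of a disturbance in organismal or cellular homeostasis, usually, but not necessarily, exogenous (e.g. temperature, humidity, ionizing radiation)." [GOC:fixture]
is_a: GO:0050896

[Term]
id: GO:0006952
name: defense response
namespace: biological_process
is_a: GO:0006950

[Term]
id: GO:0006974
name: cellular response to DNA damage stimulus
namespace: biological_process
is_a: GO:0006950
is_a: GO:0009987

[Term]
id: GO:0006979
name: response to oxidative stress
namespace: biological_process
is_a: GO:0006950

[Term]
id: GO:0007600
name: sensory perception
namespace: biological_process
is_a: GO:0050877

[Term]
id: GO:0007605
name: sensory perception of sound
namespace: biological_process
is_a: GO:0007600

[Term]
id: GO:0007610
name: behavior
namespace: biological_process
def: "The internally coordinated responses of whole living organisms to internal or external stimuli." [GOC:fixture]
is_a: GO:0008150

[Term]
id: GO:0007623
name: circadian rhythm
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0007630
name: jump response
namespace: biological_process
is_a: GO:0007610

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0009266
name: response to temperature stimulus
namespace: biological_process
is_a: GO:0009628

[Term]
id: GO:0009314
name: response to radiation
namespace: biological_process
is_a: GO:0009628

[Term]
id: GO:0009408
name: response to heat
namespace: biological_process
is_a: GO:0006950
is_a: GO:0009266

[Term]
id: GO:0009409
name: response to cold
namespace: biological_process
def: "Any process that results in a change in state or activity of a cell or an organism as a result of a cold stimulus, a temperature stimulus below the optimal temperature for that organism." [GOC:fixture]
is_a: GO:0006950
is_a: GO:0009266

[Term]
id: GO:0009611
name: response to wounding
namespace: biological_process
is_a: GO:0006950

[Term]
id: GO:0009628
name: response to abiotic stimulus
namespace: biological_process
is_a: GO:0050896

[Term]
id: GO:0009987
name: cellular process
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0012501
name: programmed cell death
namespace: biological_process
is_a: GO:0009987

[Term]
id: GO:0042060
name: wound healing
namespace: biological_process
is_a: GO:0009611

[Term]
id: GO:0043067
name: regulation of programmed cell death
namespace: biological_process
is_a: GO:0065007

[Term]
id: GO:0048512
name: circadian behavior
namespace: biological_process
is_a: GO:0007610
is_a: GO:0007623

[Term]
id: GO:0050877
name: nervous system process
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0050896
name: response to stimulus
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0065007
name: biological regulation
namespace: biological_process
is_a: GO:0008150
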