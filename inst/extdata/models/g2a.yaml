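format: caulologic-model-v1
nodes:
- name: CtrA_a
  max_level: 1
- name: GcrA
  max_level: 1
- name: DnaA
  max_level: 1
- name: CcrM
  max_level: 1
- name: SciP
  max_level: 1
rules:
- target: CtrA_a
  cases:
  - GcrA>=1 -> 1
  - CcrM==0 & SciP==0 -> 1
  default: 0
- target: GcrA
  cases:
  - DnaA>=1 & CtrA_a==0 -> 1
  default: 0
- target: DnaA
  cases:
  - CtrA_a>=1 & CcrM>=1 & GcrA==0 & DnaA==0 -> 1
  default: 0
- target: CcrM
  cases:
  - CtrA_a>=1 & SciP==0 & CcrM==0 -> 1
  default: 0
- target: SciP
  cases:
  - CtrA_a>=1 & DnaA==0 -> 1
  default: 0
clamps: []
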