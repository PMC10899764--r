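name: quadruple_mutant_CC
core:
- CC
flank5_weights:
  A: 0.4
  C: 1.0
  G: 1.0
  T: 1.0
flank3_weights:
  A: 1.0
  C: 0.6
  G: 0.05
  T: 0.05
efficiency: 1.0
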