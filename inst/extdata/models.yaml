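# Published Tc-99m DMSA kidney biokinetic parameter sets.
# T_half entries may be the literal string "inf" for a non-clearing component.
# tiac_printed is the TIAC (h) published alongside each parameter set.
icrp53:
  F_S: 0.5
  a: [-1.0, 1.0]
  T_half: [1.0, "inf"]
  tiac_printed: 3.71
evans:
  F_S: 0.4
  a: [-1.0, 1.0]
  T_half: [1.0, 7.0]
  tiac_printed: 3.0
current_study:
  F_S: 0.3
  a: [-1.0, 1.2]
  T_half: [1.1, "inf"]
  tiac_printed: 2.7
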