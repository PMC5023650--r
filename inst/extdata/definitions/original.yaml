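name: original
boundary: closed
cutoffs:
  age: [47.0, 66.0]
  pf_ratio: [105.0, 158.0]
  pmax: [27.0, 30.0]
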