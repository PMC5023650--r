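name: recalibrated
boundary: closed
cutoffs:
  age: [47.0, 59.0]
  pf_ratio: [105.0, 158.0]
  pmax: [30.0, 33.0]
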