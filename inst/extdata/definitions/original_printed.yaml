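# Variant of the original score whose Pmax middle band is widened to
# [27, 33] so that the outer bands match stratum tables that print the
# top band as ">33" while leaving 30-33 unassigned.
name: original_printed
boundary: closed
cutoffs:
  age: [47.0, 66.0]
  pf_ratio: [105.0, 158.0]
  pmax: [27.0, 33.0]
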