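# Minimal glucose-limited medium for the shipped toy_flat model.
# Keys resolve against exchanged metabolite ids (or ChEBI ids); lb is the
# (negative) maximum uptake flux, ub the secretion ceiling.
name: Min-Glu
components:
- key: glc_c
  lb: -10.0
  ub: 1000.0
supplements: {}
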