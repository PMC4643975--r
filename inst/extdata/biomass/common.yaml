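# A common biomass definition for the shipped toy models: one unit of the
# precursor pool per unit growth. Keys resolve by metabolite id, then ChEBI.
name: common
stoichiometry:
  prec_c: -1.0
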