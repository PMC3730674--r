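vogels_sucrose.tsv
  In-silico rendering of Vogel's minimal medium with sucrose as the carbon
  source: the carbon source is capped at 1.5 mmol/gDW/h; the salts, trace
  elements and biotin of the published recipe are treated as non-limiting
  (cap = the global flux bound, 1000). Metabolite identifiers are generic;
  map them to the namespace of the model in use before applying
  (readMedia() + applyMedia()).
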