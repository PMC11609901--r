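# Example reference-material registry for HTC triple isotope analysis.
# Certified deltas in permil on VSMOW (d2H, d18O) / VPDB (d13C).
- id: CEL-A
  material_class: cellulose
  d2H: -130
  d13C: -28
  d18O: 22
  x_e: 0.20
  n_content_pct: 0
  s_content_pct: 0
  exchanges_h: true
- id: CEL-B
  material_class: cellulose
  d2H: -60
  d13C: -22
  d18O: 32
  x_e: 0.20
  n_content_pct: 0
  s_content_pct: 0
  exchanges_h: true
- id: SUC-A
  material_class: sugar
  d2H: -100
  d13C: -12
  d18O: 36
  x_e: 0.36
  n_content_pct: 0
  s_content_pct: 0
  exchanges_h: true
- id: PEF
  material_class: other
  d2H: -100.3
  d13C: -32.15
  x_e: 0
  n_content_pct: 0
  s_content_pct: 0
  exchanges_h: false
- id: QC-SUC
  material_class: sugar
  d2H: -85
  d13C: -25.5
  d18O: 34
  x_e: 0.36
  n_content_pct: 0
  s_content_pct: 0
  exchanges_h: true
- id: INSECT
  material_class: other
  d2H: -121.3
  d13C: -24
  d18O: 18
  x_e: 0.17
  n_content_pct: 10.42
  s_content_pct: 0.4
  exchanges_h: true
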