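# Equilibration waters: delta-2H in permil VSMOW.
- id: W1
  d2H: -160
  uncertainty: 1
- id: W2
  d2H: -412
  uncertainty: 1
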