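# Stronger-wind transport segment: 3 cm/s with tenfold vertical mixing.
# (Used with undiluted N-layer concentrations as input.)
builder: transport
params:
  velocity: 3.0
  vertical_mixing_factor: 10.0
  segment_length: 3000
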