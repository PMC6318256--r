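# Weak-wind downstream transport segment: 3 km of L1-L4 southern-type layers
# at 1 cm/s with baseline vertical mixing.
builder: transport
params:
  velocity: 1.0
  vertical_mixing_factor: 1.0
  segment_length: 3000
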