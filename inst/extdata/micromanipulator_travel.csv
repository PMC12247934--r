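axis,full_turn_mm,quarter_turn_mm
X,0.985,0.247
Y,0.996,0.250
Z,0.982,0.244
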