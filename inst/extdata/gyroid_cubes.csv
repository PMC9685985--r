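infill,modulus,spread
0.10,24.73,14
0.20,89.91,18
0.40,288.79,6
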