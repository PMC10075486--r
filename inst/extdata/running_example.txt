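species: X1 X2
X1 -> X2
X2 -> X1
2 X1 + X2 -> 3 X1
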