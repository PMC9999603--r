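P 0 0 0
F1 0 0 0
F2 0 0 0
H1 F1 P 0
H2 F2 P 0
C1 H1 H2 1
C2 H1 H2 1
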