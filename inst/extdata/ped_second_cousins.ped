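GGF 0 0 0
GGM 0 0 0
S1 GGF GGM 0
S2 GGF GGM 0
A 0 0 0
B 0 0 0
P1 S1 A 0
P2 S2 B 0
C 0 0 0
D 0 0 0
X P1 C 1
Y P2 D 1
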