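sample	marker	nA	nC	nG	nT
S1	rs1	3	0	4	0
S1	rs2	0	2	5	0
S2	rs1	6	1	0	0
S2	rs3	2	0	0	3
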