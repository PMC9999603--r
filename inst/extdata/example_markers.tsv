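marker	chrom	pos_cM	fA	fC	fG	fT
rs1	1	0.0	0.6	0.4	0	0
rs2	1	12.5	0	0.35	0.65	0
rs3	2	3.0	0.5	0	0	0.5
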