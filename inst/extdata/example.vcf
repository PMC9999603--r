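##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
1	1000	rs1	A	C	.	PASS	.	GT:AD:PL	0/0:5,1:0,30,300	0/1:3,4:40,0,50
1	2000	rs2	G	C	.	PASS	.	GT:AD:PL	0/0:7,0:0,21,210	1/1:0,6:60,18,0
2	500	rs3	T	A	.	PASS	.	GT:AD:PL	0/1:2,2:10,0,10	0/0:4,0:0,12,120
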