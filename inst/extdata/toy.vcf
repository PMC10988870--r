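##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	100	.	A	T	.	.	.	GT	0|0	0|1	1|1
1	205	rs1	C	G	.	.	.	GT	0|1	1|0	0|0
1	310	.	G	A	.	.	.	GT	1|1	0|0	0|1
1	420	.	T	C	.	.	.	GT	0|0	0|0	1|0
1	530	.	A	G	.	.	.	GT	0|1	0|1	1|1
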