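##fileformat=VCFv4.2
##contig=<ID=1>
##contig=<ID=2>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	line_001	line_002	line_003
1	1000	snp1	A	G	.	PASS	.	GT	0/0	1/1	0/0
1	2000	snp2	C	T	.	PASS	.	GT	0/1	1/1	./.
2	500	snp3	G	A	.	PASS	.	GT	1/1	0/0	1/1
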