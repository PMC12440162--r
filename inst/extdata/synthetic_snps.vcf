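##fileformat=VCFv4.2
##source=beeflow synthetic fixture (hand-written; not derived from any real dataset)
##contig=<ID=chr1,length=1000000>
##contig=<ID=chr2,length=1000000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
chr1	1001	snpA	A	G	99	PASS	.	GT	0/0	0/1	1/1
chr1	2002	snpB	C	T	99	PASS	.	GT	0/1	0/0	0/1
chr2	3003	snpC	G	A	99	PASS	.	GT	1/1	0/1	0/0
chr2	4004	snpD	T	C	99	PASS	.	GT	0/1	1/1	0/0
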