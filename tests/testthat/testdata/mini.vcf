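##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=GQX,Number=1,Type=Integer,Description="Min genotype quality over variant and non-variant">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NA00001
chr1	100	rs1	A	T	55.5	PASS	.	GT:GQ:GQX	0/1:60:48
chr1	200	.	T	TGC	41	PASS	.	GT:GQ:GQX	0/1:50:33
chr1	300	.	TGC	T	39	LowQual	.	GT:GQ:GQX	1/1:20:12
chr1	400	.	C	A,G	80	PASS	.	GT:GQ:GQX	1/2:70:66
chr1	500	.	AT	GC	50	PASS	.	GT:GQ:GQX	0/1:44:40
chr1	600	.	G	C	.	PASS	.	GT:GQ:GQX	0/1:33:30
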