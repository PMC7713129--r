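##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TOY
chr1	1000	.	A	T	99	.	.	GT:AD	0/1:30,28
chr1	2000	.	A	T,G	80	.	.	GT:AD	1/2:20,5,10
chr2	500	.	C	G	60	.	.	GT:AD	1/1:0,40
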