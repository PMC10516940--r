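##fileformat=VCFv4.2
##source=icasort-toy-fixture-synthetic
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	H522	A549
chr17	7674230	snv1	C	A	.	PASS	.	GT	1/1	0/0
chr2	47403310	snv2	G	T	.	PASS	.	GT	1/1	0/0
chr5	1295113	snv3	T	C	.	PASS	.	GT	1/1	0/0
chr7	55191822	snv4	A	G	.	PASS	.	GT	1/1	0/0
chr12	25245350	snv5	C	T	.	PASS	.	GT	1/1	0/0
chr9	5073770	multi1	G	A,T	.	PASS	.	GT	1/2	0/0
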