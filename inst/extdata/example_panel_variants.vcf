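##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Panel gene symbol">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Transcript consequence">
##INFO=<ID=SPLICE_DIST,Number=1,Type=Integer,Description="Distance into intron, 0 for exonic">
##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description="gnomAD allele frequency">
##INFO=<ID=WL,Number=1,Type=Integer,Description="Whitelisted pathogenic intronic (0/1)">
##INFO=<ID=HGVSP,Number=1,Type=String,Description="Protein notation">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AF,Number=1,Type=Float,Description="Variant allele fraction">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
2	1200345	.	G	A	67	PASS	GENE=SLC3A1;CSQ=missense;SPLICE_DIST=0;GNOMAD_AF=0.0005;WL=0;HGVSP=p.(Met467Thr)	GT:AF	0/1:0.48	0/0:.
19	1010101	.	C	T,G	55	PASS	GENE=SLC7A9;CSQ=missense;SPLICE_DIST=0;WL=0;HGVSP=p.(Gly105Arg)	GT:AF	1/2:0.51	0/1:0.44
7	888888	.	T	C	80	PASS	GENE=MADEUPGENE;CSQ=missense;SPLICE_DIST=0;GNOMAD_AF=0.001;WL=0;HGVSP=p.(Ala10Val)	GT:AF	0/1:0.5	0/0:.
X	505050	.	A	G	60	PASS	GENE=OCRL;CSQ=missense;SPLICE_DIST=0;GNOMAD_AF=0.0001;WL=0;HGVSP=p.(Arg301Cys)	GT:AF	1:0.98	0/0:.
9	2022022	.	C	T	90	PASS	GENE=SLC34A3;CSQ=intronic;SPLICE_DIST=25;GNOMAD_AF=0.002;WL=1;HGVSP=.	GT:AF	0/0:.	0/1:0.47
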