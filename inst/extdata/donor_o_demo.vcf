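##fileformat=VCFv4.2
##source=chimerase-simulator
##contig=<ID=chr1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	OOO
chr1	642	.	T	G	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	761	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	888	.	C	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	2541	.	A	T	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	2866	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	2990	.	C	G	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	4511	.	T	A	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	4702	.	C	A	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	4813	.	C	A	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	6127	.	C	T	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	6323	.	A	T	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	6553	.	T	A	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	8526	.	G	T	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	8633	.	A	G	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	8957	.	A	C	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	10456	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	10498	.	A	G	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	10959	.	G	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	12180	.	C	A	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	12969	.	C	A	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	12981	.	A	C	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	14057	.	C	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	14465	.	C	G	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	14518	.	C	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	16104	.	C	G	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	16182	.	T	G	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	16212	.	C	G	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	18393	.	G	C	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	18677	.	C	A	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	18925	.	G	A	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	20409	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	20738	.	C	T	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	20832	.	C	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	22246	.	T	A	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	22514	.	C	A	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	22709	.	A	G	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	24333	.	T	G	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	24456	.	G	A	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	24896	.	A	C	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	26240	.	G	T	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	26905	.	G	A	60	PASS	.	GT:AD:DP	0/0:40,0:40
chr1	26979	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	28011	.	C	.	60	PASS	.	GT:AD:DP	0/0:40:40
chr1	28030	.	T	.	60	PASS	.	GT:AD:DP	0/0:40:40
chr1	28041	.	T	.	60	PASS	.	GT:AD:DP	0/0:40:40
chr1	28053	.	G	.	60	PASS	.	GT:AD:DP	0/0:40:40
chr1	28059	.	A	.	60	PASS	.	GT:AD:DP	0/0:40:40
chr1	28064	.	C	G	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	28080	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	28086	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	28093	.	T	G	60	PASS	.	GT:AD:DP	1/1:0,40:40
chr1	28096	.	C	A	60	PASS	.	GT:AD:DP	1/1:0,40:40
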