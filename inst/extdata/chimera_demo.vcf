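##fileformat=VCFv4.2
##source=chimerase-simulator
##contig=<ID=chr1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	OCC
chr1	642	.	T	G	60	PASS	.	GT:AD:DP	0/1:11,38:49
chr1	761	.	A	T	60	PASS	.	GT:AD:DP	0/1:43,8:51
chr1	888	.	C	T	60	PASS	.	GT:AD:DP	0/1:43,16:59
chr1	2541	.	A	T	60	PASS	.	GT:AD:DP	0/1:15,42:57
chr1	2866	.	A	T	60	PASS	.	GT:AD:DP	0/1:33,12:45
chr1	2990	.	C	G	60	PASS	.	GT:AD:DP	0/1:39,14:53
chr1	4511	.	T	A	60	PASS	.	GT:AD:DP	0/1:20,37:57
chr1	4702	.	C	A	60	PASS	.	GT:AD:DP	0/1:33,13:46
chr1	4813	.	C	A	60	PASS	.	GT:AD:DP	0/1:12,42:54
chr1	6127	.	C	T	60	PASS	.	GT:AD:DP	0/1:18,38:56
chr1	6323	.	A	T	60	PASS	.	GT:AD:DP	0/1:11,39:50
chr1	6553	.	T	A	60	PASS	.	GT:AD:DP	0/1:14,35:49
chr1	8526	.	G	T	60	PASS	.	GT:AD:DP	0/1:16,30:46
chr1	8633	.	A	G	60	PASS	.	GT:AD:DP	0/1:45,16:61
chr1	8957	.	A	C	60	PASS	.	GT:AD:DP	0/1:13,47:60
chr1	10456	.	A	T	60	PASS	.	GT:AD:DP	0/1:0,33:33
chr1	10498	.	A	G	60	PASS	.	GT:AD:DP	0/1:0,43:43
chr1	10959	.	G	T	60	PASS	.	GT:AD:DP	0/1:0,51:51
chr1	12180	.	C	A	60	PASS	.	GT:AD:DP	0/1:33,13:46
chr1	12969	.	C	A	60	PASS	.	GT:AD:DP	0/1:13,26:39
chr1	12981	.	A	C	60	PASS	.	GT:AD:DP	0/1:34,13:47
chr1	14057	.	C	T	60	PASS	.	GT:AD:DP	0/1:39,8:47
chr1	14465	.	C	G	60	PASS	.	GT:AD:DP	0/1:42,14:56
chr1	14518	.	C	T	60	PASS	.	GT:AD:DP	0/1:35,17:52
chr1	16104	.	C	G	60	PASS	.	GT:AD:DP	0/1:14,40:54
chr1	16182	.	T	G	60	PASS	.	GT:AD:DP	0/1:14,35:49
chr1	16212	.	C	G	60	PASS	.	GT:AD:DP	0/1:8,33:41
chr1	18393	.	G	C	60	PASS	.	GT:AD:DP	0/1:12,42:54
chr1	18677	.	C	A	60	PASS	.	GT:AD:DP	0/1:26,11:37
chr1	18925	.	G	A	60	PASS	.	GT:AD:DP	0/1:12,37:49
chr1	20409	.	A	T	60	PASS	.	GT:AD:DP	0/1:44,0:44
chr1	20738	.	C	T	60	PASS	.	GT:AD:DP	0/1:0,58:58
chr1	20832	.	C	T	60	PASS	.	GT:AD:DP	0/1:39,0:39
chr1	22246	.	T	A	60	PASS	.	GT:AD:DP	0/1:42,15:57
chr1	22514	.	C	A	60	PASS	.	GT:AD:DP	0/1:48,19:67
chr1	22709	.	A	G	60	PASS	.	GT:AD:DP	0/1:29,7:36
chr1	24333	.	T	G	60	PASS	.	GT:AD:DP	0/1:51,1:52
chr1	24456	.	G	A	60	PASS	.	GT:AD:DP	0/1:42,0:42
chr1	24896	.	A	C	60	PASS	.	GT:AD:DP	0/1:0,58:58
chr1	26240	.	G	T	60	PASS	.	GT:AD:DP	0/1:0,35:35
chr1	26905	.	G	A	60	PASS	.	GT:AD:DP	0/1:0,52:52
chr1	26979	.	A	T	60	PASS	.	GT:AD:DP	0/1:58,1:59
chr1	28011	.	C	.	60	PASS	.	GT:AD:DP	0/0:51:51
chr1	28030	.	T	.	60	PASS	.	GT:AD:DP	0/0:47:47
chr1	28041	.	T	.	60	PASS	.	GT:AD:DP	0/0:44:44
chr1	28053	.	G	.	60	PASS	.	GT:AD:DP	0/0:60:60
chr1	28059	.	A	.	60	PASS	.	GT:AD:DP	0/0:54:54
chr1	28064	.	C	G	60	PASS	.	GT:AD:DP	1/1:0,49:49
chr1	28080	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,51:51
chr1	28086	.	A	T	60	PASS	.	GT:AD:DP	1/1:0,44:44
chr1	28093	.	T	G	60	PASS	.	GT:AD:DP	1/1:0,45:45
chr1	28096	.	C	A	60	PASS	.	GT:AD:DP	1/1:0,56:56
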