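chr1	0	1000	gene0001	0	+
chr1	2000	3000	gene0002	0	+
chr1	4000	5000	gene0003	0	+
chr1	6000	7000	gene0004	0	+
chr1	8000	9000	gene0005	0	+
chr1	10000	11000	gene0006	0	+
chr1	12000	13000	gene0007	0	+
chr1	14000	15000	gene0008	0	+
chr1	16000	17000	gene0009	0	+
chr1	18000	19000	gene0010	0	+
chr1	20000	21000	gene0011	0	+
chr1	22000	23000	gene0012	0	+
chr1	24000	25000	PDF1	0	+
chr1	26000	27000	SYS	0	+
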