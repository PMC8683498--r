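##fileformat=VCFv4.2
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	peritoneal
1	100	.	A	T	.	PASS	GENE=EGFR_del19	AD:DP	95,44:139
1	200	.	A	T	.	PASS	GENE=C0_m2	AD:DP	85,53:138
1	300	.	A	T	.	PASS	GENE=C0_m3	AD:DP	87,49:136
1	400	.	A	T	.	PASS	GENE=C0_m4	AD:DP	95,56:151
1	1000100	.	A	T	.	PASS	GENE=EGFR_T790M	AD:DP	103,53:156
1	1000200	.	A	T	.	PASS	GENE=C1_m2	AD:DP	83,58:141
1	1000300	.	A	T	.	PASS	GENE=C1_m3	AD:DP	89,40:129
1	1000400	.	A	T	.	PASS	GENE=C1_m4	AD:DP	98,51:149
1	2000100	.	A	T	.	PASS	GENE=C3_m1	AD:DP	136,19:155
1	2000200	.	A	T	.	PASS	GENE=C3_m2	AD:DP	125,23:148
1	2000300	.	A	T	.	PASS	GENE=C3_m3	AD:DP	131,22:153
1	2000400	.	A	T	.	PASS	GENE=C3_m4	AD:DP	126,17:143
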