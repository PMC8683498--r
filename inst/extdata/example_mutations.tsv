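sample_id	chrom	pos	ref	alt	alt_reads	total_reads	gene
peritoneal	1	100	A	T	44	139	EGFR_del19
peritoneal	1	200	A	T	53	138	C0_m2
peritoneal	1	300	A	T	49	136	C0_m3
peritoneal	1	400	A	T	56	151	C0_m4
peritoneal	1	1000100	A	T	53	156	EGFR_T790M
peritoneal	1	1000200	A	T	58	141	C1_m2
peritoneal	1	1000300	A	T	40	129	C1_m3
peritoneal	1	1000400	A	T	51	149	C1_m4
peritoneal	1	2000100	A	T	19	155	C3_m1
peritoneal	1	2000200	A	T	23	148	C3_m2
peritoneal	1	2000300	A	T	22	153	C3_m3
peritoneal	1	2000400	A	T	17	143	C3_m4
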