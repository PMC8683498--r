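sample_id	chrom	start	end	total_cn
peritoneal	1	1	2000000	2
peritoneal	1	2000001	5000000	3
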