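patient_id	time_days	event
P01	636	0
P04	287	1
P12	101	1
P13	239	1
P14	359	1
P15	219	1
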