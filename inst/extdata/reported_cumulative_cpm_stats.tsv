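cohort	sex	n	min	median	mean	max
tissue	male	30	30.92	46.76	80.65	250.85
tissue	female	36	0	0	0.03	0.37
blastocyst	male	14	22.02	171.32	161.38	275.28
blastocyst	female	8	0	0	0	0
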