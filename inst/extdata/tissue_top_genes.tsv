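gene_id	symbol	logFC	logCPM	F	P	chry_start	chry_end
ENSBIXG00000029763	OFD1	11.27	14.75	2118.43	7.92e-37	6953027	7017526
ENSBIXG00000029788	NA	9.71	14.55	1046.01	3.99e-46	7419104	7602856
ENSBIXG00000029774	ZRSR2	10.98	14.47	813.87	1.34e-28	7305910	7361376
ENSBIXG00000029892	NA	8.46	15.50	707.08	3.41e-40	8054318	8104065
ENSBIXG00000029986	NA	9.59	13.15	429.26	2.75e-23	10463946	10554936
ENSBIXG00000029770	NA	7.97	16.16	341.26	4.12e-29	7099749	7248718
ENSBIXG00000029886	NA	-1.95	18.42	320.06	6.13e-29	7835303	7835773
ENSBIXG00000029889	NA	6.60	15.14	228.70	5.33e-23	7966867	8040039
ENSBIXG00000029864	NA	6.73	15.57	210.27	4.26e-22	7648102	7686255
ENSBIXG00000030021	NA	-2.46	14.86	172.28	3.28e-21	11907972	11908877
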