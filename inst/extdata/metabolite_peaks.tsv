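name	kegg_id	species_bias	base_conc	center_ppm	relative_area	linewidth_ppm
betaine	C00719	A_lixula	1.0	3.26	0.75	0.003
betaine	C00719	A_lixula	1.0	3.90	0.25	0.003
taurine	C00245	A_lixula	1.0	3.42	0.55	0.003
taurine	C00245	A_lixula	1.0	3.25	0.45	0.003
sarcosine	C00213	A_lixula	1.0	2.73	0.60	0.003
sarcosine	C00213	A_lixula	1.0	3.60	0.40	0.003
trimethylamine	C00565	A_lixula	1.0	2.89	1.00	0.003
trimethylamine N-oxide	C01104	A_lixula	1.0	3.27	1.00	0.003
carnitine	C00318	A_lixula	1.0	3.23	0.60	0.003
carnitine	C00318	A_lixula	1.0	2.43	0.40	0.003
creatine	C00300	A_lixula	1.0	3.03	0.60	0.003
creatine	C00300	A_lixula	1.0	3.93	0.40	0.003
malonate	C00383	A_lixula	1.0	3.11	1.00	0.003
methylmalonate	C02170	A_lixula	1.0	1.21	0.70	0.003
methylmalonate	C02170	A_lixula	1.0	3.17	0.30	0.003
uridine	C00299	A_lixula	1.0	5.90	0.55	0.003
uridine	C00299	A_lixula	1.0	7.87	0.45	0.003
xanthine	C00385	A_lixula	1.0	7.89	1.00	0.003
lysine	C00047	P_lividus	1.5	1.72	0.50	0.003
lysine	C00047	P_lividus	1.5	3.01	0.30	0.003
lysine	C00047	P_lividus	1.5	1.47	0.20	0.003
glycine	C00037	P_lividus	1.5	3.56	1.00	0.003
glutamine	C00064	P_lividus	1.5	2.45	0.50	0.003
glutamine	C00064	P_lividus	1.5	2.14	0.30	0.003
glutamine	C00064	P_lividus	1.5	3.77	0.20	0.003
formaldehyde	C00067	P_lividus	1.0	9.62	1.00	0.003
methanol	C00132	P_lividus	1.0	3.36	1.00	0.003
3-carboxypropyl-trimethylammonium	C01181	P_lividus	1.0	3.13	0.60	0.003
3-carboxypropyl-trimethylammonium	C01181	P_lividus	1.0	2.34	0.40	0.003
fatty acids		P_lividus	3.5	1.30	0.60	0.050
fatty acids		P_lividus	3.5	0.90	0.40	0.040
kynurenine	C00328	shared	0.8	7.30	0.50	0.003
kynurenine	C00328	shared	0.8	6.88	0.50	0.003
alanine	C00041	shared	1.0	1.48	1.00	0.003
lactate	C00186	shared	1.2	1.33	0.75	0.003
lactate	C00186	shared	1.2	4.11	0.25	0.003
acetate	C00033	shared	1.0	1.92	1.00	0.003
succinate	C00042	shared	1.0	2.41	1.00	0.003
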