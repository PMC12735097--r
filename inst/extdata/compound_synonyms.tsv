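query_name	kegg_id	canonical_name
betaine	C00719	Betaine
glycine betaine	C00719	Betaine
trimethylglycine	C00719	Betaine
taurine	C00245	Taurine
sarcosine	C00213	Sarcosine
n-methylglycine	C00213	Sarcosine
trimethylamine	C00565	Trimethylamine
tma	C00565	Trimethylamine
trimethylamine n-oxide	C01104	Trimethylamine N-oxide
trimethylamine-n-oxide	C01104	Trimethylamine N-oxide
tmao	C01104	Trimethylamine N-oxide
carnitine	C00318	L-Carnitine
l-carnitine	C00318	L-Carnitine
creatine	C00300	Creatine
malonate	C00383	Malonate
malonic acid	C00383	Malonate
methylmalonate	C02170	Methylmalonate
methylmalonic acid	C02170	Methylmalonate
uridine	C00299	Uridine
xanthine	C00385	Xanthine
lysine	C00047	L-Lysine
l-lysine	C00047	L-Lysine
glycine	C00037	Glycine
glutamine	C00064	L-Glutamine
l-glutamine	C00064	L-Glutamine
formaldehyde	C00067	Formaldehyde
methanol	C00132	Methanol
3-carboxypropyl-trimethylammonium	C01181	4-Trimethylammoniobutanoate
3-cptma	C01181	4-Trimethylammoniobutanoate
gamma-butyrobetaine	C01181	4-Trimethylammoniobutanoate
4-trimethylammoniobutanoate	C01181	4-Trimethylammoniobutanoate
kynurenine	C00328	L-Kynurenine
l-kynurenine	C00328	L-Kynurenine
alanine	C00041	L-Alanine
l-alanine	C00041	L-Alanine
lactate	C00186	L-Lactate
lactic acid	C00186	L-Lactate
acetate	C00033	Acetate
acetic acid	C00033	Acetate
succinate	C00042	Succinate
succinic acid	C00042	Succinate
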