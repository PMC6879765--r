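cancer_type	sex	n_total	n_mut	rate_per_100k
ESCA	female	27	19	1.7
ESCA	male	158	137	7.6
LIHC	female	121	26	4.3
LIHC	male	252	89	12.7
BLCA	female	108	56	8.7
BLCA	male	303	147	35.8
HNSC	female	138	98	6.3
HNSC	male	371	267	16.5
LUSC	female	129	102	7.4
LUSC	male	362	323	17
SKCM	female	179	23	16.8
SKCM	male	286	48	28.2
STAD	female	157	74	5.3
STAD	male	280	139	10.1
LGG	female	227	98	5
LGG	male	281	141	7.2
READ	female	77	57	9.7
READ	male	89	70	15.3
COAD	female	215	114	27.4
COAD	male	234	138	33.5
PAAD	female	79	51	11
PAAD	male	102	66	14
LUAD	female	277	143	17.4
LUAD	male	239	129	21.7
KIRC	female	179	5	10.8
KIRC	male	314	5	21.3
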