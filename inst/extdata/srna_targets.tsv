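srna_id	target_gene_id	function	rna_log2fc	rna_padj	ribo_log2fc	ribo_padj	te_log2fc	te_padj	tpm_rna_control	tpm_rna_stress	tpm_ribo_control	tpm_ribo_stress
sRNA_58	HVO_RS04540	Hypothetical protein	-1.21	0.00	-1.21	0.00	-0.02	0.98	326.20	169.80	370.97	208.87
sRNA_58	HVO_RS13165	ABC transporter permease	-1.64	0.00	-1.27	0.00	0.36	0.51	640.15	188.77	85.81	45.53
sRNA_58	HVO_RS17485	D-2-hydroxyacid dehydrogenase	-1.01	0.00	-1.60	0.00	-0.61	0.07	27.50	47.10	58.33	27.88
sRNA_58	HVO_RS17805	Hypothetical protein	1.00	0.00	1.46	0.00	0.45	0.45	54.93	91.69	36.61	98.47
sRNA_58	HVO_RS19470	Hypothetical protein	1.33	0.01	-0.65	0.05	-2.01	0.01	7.57	15.74	55.04	44.71
sRNA_77	HVO_RS05320	YccF domain-containing protein	1.01	0.00	1.37	0.00	0.34	0.62	26.87	53.00	37.93	121.84
sRNA_77	HVO_RS06805	Co-chaperone YbbN	0.62	0.06	-0.66	0.03	-1.30	0.01	1088.48	1614.45	2937.95	2326.41
sRNA_77	HVO_RS07705	Hypothetical protein	-0.52	0.09	0.80	0.07	1.31	0.04	51.84	33.24	11.22	23.01
sRNA_77	HVO_RS08415	Amidohydrolase family protein	-0.88	0.00	-1.87	0.00	-1.01	0.03	82.41	82.17	87.53	55.80
sRNA_77	HVO_RS09105	2Fe-2S domain-containing protein	-0.24	0.31	-1.24	0.00	-1.01	0.05	67.63	53.64	76.35	40.75
sRNA_77	HVO_RS11380	Hypothetical protein	1.06	0.00	2.71	0.00	1.63	0.04	21.14	49.53	68.11	579.99
sRNA_77	HVO_RS11455	BMP family protein	-0.72	0.00	-1.78	0.00	-1.08	0.05	1322.62	720.75	1618.05	586.70
sRNA_77	HVO_RS13145	Hypothetical protein	0.93	0.00	1.06	0.00	0.11	0.86	193.21	286.04	47.28	123.46
sRNA_77	HVO_RS14580	Dehydrorhamnose epimerase family protein	-0.76	0.03	-1.88	0.00	-1.14	0.07	1726.87	885.36	986.87	329.83
sRNA_77	HVO_RS15315	Hypothetical protein	-0.73	0.00	0.74	0.03	1.46	0.00	133.96	75.10	13.40	25.06
sRNA_77	HVO_RS17930	30S ribosomal protein S28e	-1.01	0.00	-1.63	0.00	-0.63	0.13	8234.66	3814.46	1902.49	770.44
sRNA_77	HVO_RS18350	Hypothetical protein	1.10	0.00	1.19	0.02	0.07	0.94	19.56	38.77	6.65	17.79
sRNA_77	HVO_RS18595	GNAT family N-acetyltransferase	0.27	0.39	1.05	0.00	0.76	0.12	30.92	27.85	9.31	23.79
sRNA_77	HVO_RS18740	Hypothetical protein	0.16	0.66	1.18	0.00	0.99	0.08	68.49	68.32	17.95	42.57
sRNA_77	HVO_RS20570	Rubrerythrin-like domain-containing protein	0.97	0.00	3.78	0.00	2.79	0.00	50.42	49.15	17.52	161.98
sRNA_83	HVO_RS00230	Methyltransferase	-1.08	0.00	-1.08	0.00	-0.01	0.98	219.52	94.40	163.37	97.06
sRNA_83	HVO_RS00700	ABC transporter substrate-binding protein	-2.13	0.00	-2.70	0.00	-0.59	0.42	190.15	38.32	819.59	157.72
sRNA_83	HVO_RS01670	Racemase enzyme family protein	1.66	0.00	1.20	0.01	-0.47	0.60	4.57	12.69	6.18	18.40
sRNA_83	HVO_RS03935	Ring-cleaving dioxygenase	0.98	0.00	1.44	0.00	0.44	0.36	36.14	63.65	24.10	83.36
sRNA_83	HVO_RS04155	Hypothetical protein	0.96	0.08	2.51	0.00	1.55	0.09	36.47	27.77	18.03	36.31
sRNA_83	HVO_RS04735	Hypothetical protein	-0.12	0.72	1.10	0.00	1.21	0.01	50.36	45.95	18.86	51.67
sRNA_83	HVO_RS05345	Thermosome subunit alpha	-1.06	0.00	-1.58	0.00	-0.53	0.37	4645.21	2047.07	6582.65	2681.76
sRNA_83	HVO_RS08545	SPFH domain-containing protein	0.46	0.04	1.25	0.00	0.77	0.10	295.03	436.26	65.36	202.53
sRNA_83	HVO_RS08645	NAD(P)-dependent dehydrogenase	-0.74	0.00	-1.63	0.00	-0.91	0.01	143.06	78.46	197.19	80.87
sRNA_83	HVO_RS13905	Serine--tRNA ligase	-0.51	0.02	-1.27	0.00	-0.77	0.07	384.53	246.71	547.21	295.37
sRNA_83	HVO_RS13930	SIMPL domain-containing protein	0.99	0.00	1.69	0.00	0.68	0.17	65.12	120.33	24.14	91.85
sRNA_83	HVO_RS17570	HpcH/HpaI aldolase/citrate lyase family protein	0.96	0.01	1.87	0.00	0.89	0.38	133.65	232.04	49.88	213.11
sRNA_83	HVO_RS19230	ABC transporter ATP-binding protein	-1.35	0.00	-1.65	0.00	-0.32	0.55	38.24	18.34	66.16	27.28
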