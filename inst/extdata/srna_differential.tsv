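gene_id	rna_log2fc	rna_padj	ribo_log2fc	ribo_padj	te_log2fc	te_padj	tpm_rna_control	tpm_rna_stress	tpm_ribo_control	tpm_ribo_stress	coding_cluster_control	coding_cluster_stress	annotated_protein	arcpp_detected	ms_detected
sRNA_20	1.21	0.00	2.63	0.00	1.41	0.04	40.22	88.01	68.74	537.73	Yes	Yes	Yes	No	No
sRNA_34	-0.44	0.22	-1.12	0.00	-0.70	0.26	19.44	15.34	12.93	7.52	Yes	No	No	NA	No
sRNA_41	-0.93	0.00	-1.18	0.00	-0.27	0.66	46.64	24.21	11.62	6.65	No	No	Yes	Yes	No
sRNA_49	2.23	0.00	1.74	0.00	-0.50	0.57	37.41	195.67	127.06	525.30	No	No	No	NA	No
sRNA_58	0.40	0.37	1.23	0.01	0.81	0.39	21.45	34.76	41.31	135.96	No	No	No	NA	No
sRNA_60	-0.12	0.94	1.72	0.00	1.82	0.28	2491.07	1996.40	382.05	568.67	NA	No	No	NA	No
sRNA_61	-0.90	0.04	0.59	0.10	1.48	0.04	4496.30	2243.82	1843.17	3350.74	Yes	Yes	No	NA	No
sRNA_62	2.24	0.00	3.15	0.00	0.89	0.42	17.24	79.53	4.06	45.72	No	Yes	No	NA	No
sRNA_71	-0.31	0.38	1.35	0.05	1.63	0.04	76.87	105.29	8.57	27.23	NA	NA	No	NA	No
sRNA_77	0.90	0.04	2.57	0.00	1.66	0.10	23.84	43.05	3.76	13.07	NA	No	No	NA	No
sRNA_83	0.06	0.89	1.59	0.00	1.52	0.03	284.91	266.25	22.57	81.26	No	No	No	NA	No
sRNA_95	1.14	0.00	1.61	0.00	0.46	0.56	21.16	45.04	9.43	33.82	No	No	No	NA	No
sRNA_96	1.65	0.00	1.59	0.00	-0.08	0.92	51.26	140.20	5.59	19.10	Yes	Yes	No	NA	No
sRNA_CD	0.95	0.01	1.50	0.00	0.53	0.44	83.53	141.43	168.64	569.29	No	Yes	Yes	Yes	No
sRNA_JD	0.68	0.20	1.33	0.01	0.64	0.57	200.14	301.88	162.34	493.83	Yes	Yes	Yes	Yes	Yes
sRNA_KL	0.16	0.57	-1.93	0.00	-2.12	0.00	129.94	136.19	1203.27	401.61	Yes	Yes	Yes	Yes	Yes
sRNA_SHOxi	2.46	0.00	2.89	0.00	0.42	0.72	341.52	1738.88	218.70	2017.74	Yes	No	No	NA	No
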