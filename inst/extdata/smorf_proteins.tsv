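status	gene_id	location	size_aa	start_codon	stop_codon	stop_within_region	rna_tpm_control	rna_tpm_stress	ribo_tpm_control	ribo_tpm_stress
novel	sRNA_7	pHV3	31	CTG	TAG	No	4.44	6.42	2.04	2.94
novel	sRNA_23	pHV4	70	CTG	TGA	Yes	11.55	17.46	5.86	12.98
novel	sRNA_80	chr	40	ATG	TAG	Yes	45.64	26.89	36.47	38.61
annotated	sRNA_JD	chr	56	ATG	TAA	Yes	203.29	307.16	163.10	497.56
annotated	sRNA_KL	chr	57	ATG	TAA	No	131.68	138.46	1207.81	405.01
annotated	sRNA_81	chr	58	CTG	TAA	Yes	35.83	20.57	30.80	25.79
annotated	sRNA_93	pHV1	116	ATG	TAG	Yes	262.20	276.16	627.41	421.53
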