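type	gene_id	location	srna_length_nt	smorf_size_aa	stop_in_region	rna_tpm_control	rna_tpm_stress	ribo_tpm_control	ribo_tpm_stress
MS-detected	sRNA_KL	chr	175	57	Yes	131.68	138.46	1207.81	405.01
MS-detected	sRNA_93	pHV1	507	116	Yes	262.20	276.16	627.41	421.53
Putative smORF	sRNA_38	pHV4	56	16	Yes	18.19	40.62	40.61	120.04
Putative smORF	sRNA_83	chr	182	55	Yes	288.90	270.63	22.64	81.98
Putative smORF	sRNA_20_ORF2	pHV4	189	21	Yes	40.77	89.47	68.98	542.12
Putative smORF	sRNA_20_ORF4	pHV4	189	34	Yes	40.77	89.47	68.98	542.12
High ribosome occupancy	sRNA_61	chr	111	32	No	4565.10	2281.40	1850.99	3381.31
High ribosome occupancy	SHOxi	pHV3	254	73	No	346.33	1767.52	219.35	2034.76
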