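srna_id	target_gene_id	interaction_pvalue
sRNA_58	HVO_RS04540	0.001
sRNA_58	HVO_RS13165	0.001
sRNA_58	HVO_RS17485	0.001
sRNA_58	HVO_RS17805	0.001
sRNA_58	HVO_RS19470	0.001
sRNA_77	HVO_RS05320	0.001
sRNA_77	HVO_RS06805	0.001
sRNA_77	HVO_RS07705	0.001
sRNA_77	HVO_RS08415	0.001
sRNA_77	HVO_RS09105	0.001
sRNA_77	HVO_RS11380	0.001
sRNA_77	HVO_RS11455	0.001
sRNA_77	HVO_RS13145	0.001
sRNA_77	HVO_RS14580	0.001
sRNA_77	HVO_RS15315	0.001
sRNA_77	HVO_RS17930	0.001
sRNA_77	HVO_RS18350	0.001
sRNA_77	HVO_RS18595	0.001
sRNA_77	HVO_RS18740	0.001
sRNA_77	HVO_RS20570	0.001
sRNA_83	HVO_RS00230	0.001
sRNA_83	HVO_RS00700	0.001
sRNA_83	HVO_RS01670	0.001
sRNA_83	HVO_RS03935	0.001
sRNA_83	HVO_RS04155	0.001
sRNA_83	HVO_RS04735	0.001
sRNA_83	HVO_RS05345	0.001
sRNA_83	HVO_RS08545	0.001
sRNA_83	HVO_RS08645	0.001
sRNA_83	HVO_RS13905	0.001
sRNA_83	HVO_RS13930	0.001
sRNA_83	HVO_RS17570	0.001
sRNA_83	HVO_RS19230	0.001
sRNA_58	synth_target_58_01	0.005
sRNA_58	synth_target_58_02	0.005
sRNA_58	synth_target_58_03	0.005
sRNA_58	synth_target_58_04	0.005
sRNA_58	synth_target_58_05	0.005
sRNA_58	synth_target_58_06	0.005
sRNA_58	synth_target_58_07	0.005
sRNA_58	synth_target_58_08	0.005
sRNA_58	synth_target_58_09	0.005
sRNA_58	synth_target_58_10	0.005
sRNA_58	synth_target_58_11	0.005
sRNA_58	synth_target_58_12	0.005
sRNA_58	synth_target_58_13	0.005
sRNA_58	synth_target_58_14	0.005
sRNA_58	synth_target_58_15	0.005
sRNA_58	synth_target_58_16	0.005
sRNA_58	synth_target_58_17	0.005
sRNA_58	synth_target_58_18	0.005
sRNA_58	synth_target_58_19	0.005
sRNA_58	synth_target_58_20	0.005
sRNA_58	synth_target_58_21	0.005
sRNA_58	synth_target_58_22	0.005
sRNA_58	synth_target_58_23	0.005
sRNA_58	synth_target_58_24	0.005
sRNA_77	synth_target_77_01	0.005
sRNA_77	synth_target_77_02	0.005
sRNA_77	synth_target_77_03	0.005
sRNA_77	synth_target_77_04	0.005
sRNA_77	synth_target_77_05	0.005
sRNA_77	synth_target_77_06	0.005
sRNA_77	synth_target_77_07	0.005
sRNA_77	synth_target_77_08	0.005
sRNA_77	synth_target_77_09	0.005
sRNA_77	synth_target_77_10	0.005
sRNA_77	synth_target_77_11	0.005
sRNA_77	synth_target_77_12	0.005
sRNA_77	synth_target_77_13	0.005
sRNA_77	synth_target_77_14	0.005
sRNA_77	synth_target_77_15	0.005
sRNA_77	synth_target_77_16	0.005
sRNA_77	synth_target_77_17	0.005
sRNA_77	synth_target_77_18	0.005
sRNA_77	synth_target_77_19	0.005
sRNA_77	synth_target_77_20	0.005
sRNA_77	synth_target_77_21	0.005
sRNA_77	synth_target_77_22	0.005
sRNA_77	synth_target_77_23	0.005
sRNA_77	synth_target_77_24	0.005
sRNA_77	synth_target_77_25	0.005
sRNA_77	synth_target_77_26	0.005
sRNA_77	synth_target_77_27	0.005
sRNA_83	synth_target_83_01	0.005
sRNA_83	synth_target_83_02	0.005
sRNA_83	synth_target_83_03	0.005
sRNA_83	synth_target_83_04	0.005
sRNA_83	synth_target_83_05	0.005
sRNA_83	synth_target_83_06	0.005
sRNA_83	synth_target_83_07	0.005
sRNA_83	synth_target_83_08	0.005
sRNA_83	synth_target_83_09	0.005
sRNA_83	synth_target_83_10	0.005
sRNA_83	synth_target_83_11	0.005
sRNA_83	synth_target_83_12	0.005
sRNA_83	synth_target_83_13	0.005
sRNA_83	synth_target_83_14	0.005
sRNA_83	synth_target_83_15	0.005
sRNA_83	synth_target_83_16	0.005
sRNA_83	synth_target_83_17	0.005
sRNA_83	synth_target_83_18	0.005
sRNA_83	synth_target_83_19	0.005
sRNA_83	synth_target_83_20	0.005
sRNA_83	synth_target_83_21	0.005
sRNA_83	synth_target_83_22	0.005
sRNA_83	synth_target_83_23	0.005
sRNA_83	synth_target_83_24	0.005
sRNA_83	synth_target_83_25	0.005
sRNA_83	synth_target_83_26	0.005
sRNA_83	synth_target_83_27	0.005
sRNA_83	synth_target_83_28	0.005
sRNA_83	synth_target_83_29	0.005
sRNA_83	synth_target_83_30	0.005
sRNA_83	synth_target_83_31	0.005
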