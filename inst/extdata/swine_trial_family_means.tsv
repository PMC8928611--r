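taxon	ConII	ConIII	PmII	PmIII	PmPII	PmPIII
Actinobacteria	2.26	0.69	3.03	1.13	2.69	0.83
Bacteroidetes	12.95	8.59	10.54	7.27	14.25	6.83
Bacteroidaceae	1.31	0.05	0.45	0.85	0.54	0.10
Porphyromonadaceae	1.16	4.38	2.21	0.28	1.31	0.38
Prevotellaceae	9.20	5.70	5.79	5.31	9.89	5.43
Firmicutes	79.39	83.67	80.65	87.56	78.55	87.71
Acidaminococcaceae	3.38	0.14	1.59	0.32	1.36	0.19
Clostridiaceae_1	2.41	4.70	1.80	4.38	2.50	2.05
Cl_Inc_Sedis_XIII	2.36	0.96	3.65	1.31	4.28	1.03
Erysipelotrichaceae	15.47	7.49	19.66	10.27	22.11	7.18
Eubacteriaceae	1.44	0.17	0.75	0.19	0.56	0.11
Lachnospiraceae	19.64	9.18	16.48	13.16	10.52	13.82
Lactobacillaceae	3.14	21.64	8.90	21.22	4.41	15.40
Peptostreptococcaceae	0.20	2.68	0.28	2.71	0.95	1.82
Ruminococcaceae	21.16	17.56	16.40	14.23	19.67	15.27
Streptococcaceae	0.35	5.15	2.05	10.32	1.39	19.60
Proteobacteria	0.73	0.77	1.11	0.37	0.45	0.17
Spirochaetes	2.06	0.55	2.02	0.56	1.40	0.29
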