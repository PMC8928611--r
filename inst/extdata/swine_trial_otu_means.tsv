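otu_id	ConII	ConIII	PmII	PmIII	PmPII	PmPIII	closest_taxon	pct_identity
Ssd-00001	0.33	10.57	2.03	11.02	1.92	6.06	Lactobacillus amylovorus	99
Ssd-00002	0.03	2.86	0.12	1.40	0.08	2.61	Lactobacillus johnsonii	99
Ssd-00014	0.07	2.24	0.20	2.26	0.70	1.45	Terrisporobacter glycolicus	97
Ssd-00019	2.11	5.43	5.25	5.73	1.48	3.97	Lactobacillus reuteri	99
Ssd-00021	1.04	0.10	0.75	0.52	1.33	0.05	Prevotella copri	95
Ssd-00039	0.27	4.46	1.72	8.95	1.12	17.19	Streptococcus alactolyticus	99
Ssd-00123	7.23	0.11	7.45	2.83	9.32	0.23	Lactobacillus vitulina	87
Ssd-00134	1.61	3.06	1.10	2.57	1.60	1.13	Clostridium saccharoperbutylacetonicum	97
Ssd-00188	0.13	0.57	0.77	1.27	0.04	2.25	Eubacterium rectale	99
Ssd-00304	0.22	0.88	0.49	1.42	0.49	0.95	Anaeromassilibacillus senegalensis	84
Ssd-00308	1.49	0.55	4.35	1.41	4.12	0.98	Holdemanella biformis	97
Ssd-00416	2.67	0.06	1.28	0.08	0.82	0.08	Phascolarctobacterium succinatutens	95
Ssd-00706	0.48	1.31	0.29	1.05	0.56	1.05	Lactobacillus paracasei	81
Ssd-00840	1.20	0.12	1.69	0.47	1.83	0.23	Collinsella aerofaciens	98
Ssd-00892	0.71	0.42	2.30	0.44	1.66	0.35	Solobacterium moorei	89
Ssd-00928	1.14	0.12	0.60	0.07	0.36	0.08	Ruminococcus gnavus	96
Ssd-00993	1.33	0.33	1.61	0.25	1.67	0.20	Faecalibacterium cylindroides	88
Ssd-01079	0.62	0.78	1.72	0.04	1.25	0.27	Mahella australiensis	84
Ssd-01080	0.31	0.19	0.53	0.13	1.59	0.21	Ihubacter massiliensis	92
Ssd-01081	1.34	0.60	0.11	0.36	0.46	0.75	Blautia pachnodae	81
Ssd-01244	2.05	0.005	0.26	0.00	0.77	0.00	Ruminococcus bromii	92
Ssd-01246	0.64	0.00	0.49	0.005	1.22	0.005	Sharpea azabuensis	97
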