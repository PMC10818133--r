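level	taxa_pair	population_pair	fst	dxy	N_ref	nu1	nu2	m	m_e	M21	M12	T_Myr	P	Q
intraspecific	Taxon2	T2TSAU-T2TSMA	0.019	NA	4548	1027	6194	1.0e-3	2.5e-4	10.6	6.4	0.037	0.94	0.056
intraspecific	Taxon3	T3OCCH-T3ONMO	0.081	NA	43561	81787	128577	1.5e-5	1.4e-6	1.3	2.0	0.45	0.94	0.060
intraspecific	Taxon5	T5CBLM-T5CBHE	0.088	NA	47903	70878	59012	2.7e-5	7.4e-6	1.9	1.6	0.37	0.90	0.10
intraspecific	Taxon1	T1CBHE-T1ONLI	0.15	NA	27679	31020	127982	1.0e-5	5.2e-6	0.32	1.35	0.38	0.88	0.12
interspecific	Taxon1-Taxon2	T1ONLI-T2TSAU	0.19	0.0085	43026	134733	156535	3.0e-6	1.5e-8	0.41	0.47	0.44	0.91	0.090
interspecific	Taxon4-Taxon5	T4CBHE-T5CBHE	0.33	0.0095	32228	91660	58706	4.2e-6	1.5e-8	0.39	0.25	0.42	0.89	0.11
interspecific	Taxon1-Taxon3	T1ONMO-T3ONMO	0.33	0.0093	15843	143123	148824	5.4e-7	5.4e-8	0.078	0.080	0.89	0.78	0.22
interspecific	Taxon1-Taxon3	T1OCCH-T3OCCH	0.34	0.0093	26159	119046	113869	1.3e-6	8.8e-8	0.16	0.15	0.54	0.82	0.18
interspecific	Taxon1-Taxon5	T1CBLM-T5CBLM	0.52	0.0091	271224	110669	89702	7.3e-8	1.8e-8	8.1e-3	6.6e-3	0.66	0.72	0.28
interspecific	Taxon1-Taxon5	T1CBHE-T5CBHE	0.52	0.0091	8282	100038	93345	2.4e-7	6.0e-8	0.024	0.022	0.92	0.72	0.28
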