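chrom	rsid	pos	cms_published	pbs_published	gene	freq_tbp	freq_du	freq_yks	n_tbp	n_du	n_yks
7	rs330394801	9366281	11.14	0.63	PHACTR1	0.93	0.33	0.06	58	25	35
14	rs345247653	48268185	10.45	0.53	SFI1	0.92	0.27	0.30	58	25	35
1	rs327305811	19895804	9.92	0.43	EPM2A	0.88	0.45	0.43	58	25	35
4	rs345409819	49294816	9.72	0.59	BCR	0.93	0.25	0.36	58	25	35
4	rs343611709	117365692	9.42	0.55	SLC30A7	0.77	0.17	0.12	58	25	35
1	rs80786074	38655025	9.21	0.59	NKAIN2	0.81	0.08	0.20	58	25	35
6	6:138801329	138801329	9.17	0.38	TNNI3K	0.76	0.01	0.31	58	25	35
1	rs344915163	203690850	9.11	0.67	PLIN2	0.75	0.02	0.03	58	25	35
18	rs333217490	40016420	9.09	0.34	BBS9	0.68	0.25	0.01	58	25	35
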