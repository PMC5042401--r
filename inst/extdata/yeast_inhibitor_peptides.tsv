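gene	sequence	control_avg	control_sem	n_control	pdr5_bortezomib_avg	pdr5_bortezomib_sem	pdr5_bortezomib_sig	snq2_bortezomib_avg	snq2_bortezomib_sem	snq2_bortezomib_sig	snq2_epoxomicin_avg	snq2_epoxomicin_sem	snq2_epoxomicin_sig	wt_bortezomib_avg	wt_bortezomib_sem	wt_bortezomib_sig
ADH1	STLPEIYEK	1.00	0.08	6	1.95	0.25	**	0.93	0.21	NS	1.02	0.22	NS			ND
APE3	SPPVDGFVGK	1.00	0.16	6	1.95	0.11	*	0.93	0.38	NS	0.85	0.39	NS			ND
APE3	SEKLQDKIKVD	1.00	0.07	6	1.42	0.21	*	1.28	0.18	NS	0.69	0.19	NS			ND
APE3	NIIADTKHGDPDNI	1.00	0.14	6	0.34	0.06	*	1.13	0.44	NS	0.94	0.09	NS			ND
ENO2	AVSKVYA	1.00	0.17	8	2.58	0.17	**	2.46	1.11	*	1.27	0.26	NS	1.53	0.63	NS
ENO2	QIGTLSESIK	1.00	0.07	8	1.68	0.19	**	0.74	0.13	NS	0.99	0.27	NS	1.18	0.18	NS
ENO2	QIGTLSESIKA	1.00	0.03	8	1.41	0.02	***	1.90	0.13	***	0.97	0.19	NS	1.21	0.21	NS
ENO2	GVELADMYHS	1.00	0.13	8	1.84	0.35	*	1.76	0.77	NS	1.59	0.01	NS	2.02	0.16	**
ENO2	TAIEKKAADAL	1.00	0.05	8	1.45	0.09	**	1.32	0.06	*	1.06	0.19	NS	1.28	0.16	NS
ENO2	GHDGKVKIGLD	1.00	0.13	8	0.93	0.04	NS	1.12	0.58	NS	0.79	0.01	NS	1.30	0.15	NS
ENO2	ADLSKSKTSPY	1.00	0.09	6	0.70	0.06	NS	1.21	0.56	NS			ND	1.20	0.07	NS
ENO2	SLDGTANKSKLGA	1.00	0.06	8	0.19	0.07	***	0.20	0.01	***	1.09	0.26	NS	1.22	0.15	NS
ENO2	SLDGTANKSKLGAN	1.00	0.08	8	1.54	0.22	*	1.25	0.21	NS	0.86	0.19	NS	1.28	0.28	NS
ENO2	SLDGTANKSKLGANA	1.00	0.08	8	0.28	0.01	*	0.24	0.02	***	1.10	0.27	NS	0.90	0.19	NS
ENO2	NLDVKDQKAVDDF	1.00	0.09	6	0.47	0.01	***	0.54	0.06	***	1.00	0.10	NS			ND
GAS1	DDVPAIEVVGNKF	1.00	0.02	6	1.09	0.17	NS	0.80	0.17	*	1.01	0.01	NS			ND
PEP4	GKFDGIL	1.00	0.14	8	5.73	0.82	***	6.70	1.07	***	1.38	0.10	NS	1.60	0.23	NS
TDH1	YDSTHGRYKGT	1.00	0.11	6	1.10	0.04	NS	0.98	0.13	NS			ND	1.40	0.45	NS
TDH3	STGVFKEL	1.00	0.16	6	2.18	0.35	*	0.82	0.10	NS	1.08	0.07	NS			ND
TPI1	VDIINSRN	1.00	0.13	8	0.59	0.02	NS	1.80	0.68	NS	1.83	0.80	NS	1.28	0.27	NS
TPI1	VKKPQVTVGAQ	1.00	0.06	8	2.70	0.04	***	2.06	0.41	***	1.19	0.46	NS	1.25	0.23	NS
TPI1	GAFTGENSVDQIK	1.00	0.16	8	1.31	0.24	NS	1.56	0.32	NS	2.02	0.04	*	1.33	0.17	NS
TPI1	GLAATPEDAQDIHA	1.00	0.08	8	0.34	0.13	**	0.53	0.08	*	1.44	0.07	*	1.14	0.13	NS
TPI1	ASGAFTGENSVDQIK	1.00	0.11	8	0.98	0.20	NS	0.91	0.13	NS	2.15	0.47	**	1.40	0.01	NS
TPI1	GAFTGENSVDQIKDVGAK	1.00	0.08	6			ND	2.40	0.59	**	1.23	0.14	NS	1.09	0.15	NS
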