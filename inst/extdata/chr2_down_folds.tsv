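gene	Fibroblast	Stem	ATII	CD8_T_BL	CD8_T_LL	Basal_cell	Duct_cell
1500012F01Rik	1.00/2.24	2.51/4.68	0.09/0.29	0.83/1.11	1.30/1.68	2.50/3.01	4.17/4.95
1600027N09Rik	0.02/0.26	0.24/0.53	3.26/2.85	5.59/4.77	6.52/5.68	6.23/5.32	6.80/5.85
1700058C13Rik	0.01/0.29	0.03/0.31	6.00/5.54	6.63/5.93	15.2/13.91	7.23/6.46	4.82/4.30
2010317E24Rik	0.71/2.34	1.58/4.04	0.03/0.47	0.23/0.70	1.38/2.34	10.45/14.81	10.14/14.46
2810408M09Rik	1.13/1.13	0.66/0.66	20.58/14.77	1.23/0.58	14.91/10.44	65.85/46.34	29.46/20.69
4921504E06Rik	0.16/0.37	0.31/0.55	6.25/5.27	0.87/0.57	8.86/7.40	11.6/9.56	9.10/7.51
6820408C15Rik	0.02/0.06	0.54/0.61	99.87/75.87	8.76/6.22	28.01/20.77	26.11/19.03	17.2/12.51
Abca2	0.77/1.04	0.51/0.73	11.84/9.81	5.21/4.07	6.05/4.84	8.82/7.01	6.99/5.55
Acvr2a	1.31/1.33	0.42/0.43	23.28/16.86	13.98/9.7	25.29/18.05	84.04/59.65	70.93/50.56
Angptl2	0.52/0.45	1.97/0.31	16.78/0.65	9.96/1.22	5.33/2.03	14.94/3.34	20.00/1.38
Api5	0.06/0.28	0.40/1.50	3.39/9.94	6.09/5.56	4.92/2.84	3.10/8.51	3.11/11.60
Arhgap1	0.30/0.39	0.05/0.84	1.45/3.21	1.27/5.61	0.44/4.59	4.67/2.81	3.64/2.84
Arpc5l	1.84/1.17	0.11/0.75	1.81/1.99	9.73/1.70	7.56/0.73	9.55/5.73	5.43/4.53
Atf2	0.15/2.57	0.26/0.39	2.39/1.58	7.92/8.55	3.92/6.73	8.87/8.38	5.91/4.74
B2m	1.13/0.44	0.57/1.06	2.50/1.63	4.18/3.06	4.50/2.19	2.32/1.70	1.22/1.32
Catsper2	1.51/0.83	0.31/1.01	14.79/2.94	24.41/9.06	27.92/4.63	19.7/10.11	15.59/6.82
Cbfa2t2	0.21/0.82	0.43/0.34	0.27/1.18	0.97/2.13	0.86/2.37	0.60/1.00	0.28/0.35
Cdca7	1.89/1.49	6.28/0.30	1.05/10.46	1.2/16.91	0.10/19.66	2.18/13.55	2.49/10.73
Cep110	1.61/0.62	0.28/0.92	0.84/0.24	7.14/0.87	4.90/0.79	5.53/0.51	2.91/0.22
Chchd5	0.45/3.93	0.13/11.43	6.34/1.55	3.16/1.67	2.13/0.35	12.54/2.84	10.66/3.24
Ciz1	0.30/2.69	0.21/0.81	1.53/0.90	0.84/7.16	0.68/4.99	7.8/5.53	4.74/2.93
Cry2	0.11/1.18	0.15/0.69	13.7/7.05	4.83/3.43	2.42/2.38	10.9/13.38	11.47/11.46
Ddx27	0.42/0.74	0.44/0.62	0.20/1.47	1.27/0.74	1.09/0.61	5.47/7.32	6.52/4.46
Ddx31	0.31/0.36	0.93/0.91	0.51/2.65	1.79/8.07	0.75/9.21	5.42/17.28	5.09/13.41
Depdc7	1.34/0.33	0.42/0.38	13.2/11.89	0.67/3.96	2.85/1.96	2.96/9.11	33.03/9.65
Dsn1	0.61/0.26	1.33/0.31	6.39/6.62	39.29/12.48	47.16/10.54	12.99/6.54	23.88/5.26
Elp4	0.76/1.09	0.25/1.12	5.62/0.30	1.29/1.37	1.03/1.21	14.19/5.74	10.08/6.88
Ext2	0.44/0.46	0.68/1.16	23.82/0.23	31.23/1.21	21.21/0.41	20.92/4.07	11.20/3.83
Fmnl2	0.18/1.37	0.15/0.44	11.91/9.50	5.60/0.20	12.75/1.80	15.11/1.84	21.28/23.52
Fubp3	0.04/0.99	0.42/1.88	14.72/5.69	34.28/34.4	32.79/41.90	93.41/11.27	73.83/20.93
Gapvd1	0.04/0.18	0.09/3.47	3.56/5.04	5.04/13.37	3.84/8.91	3.82/4.01	3.24/2.43
Gmeb2	0.30/1.39	0.70/0.70	15.73/5.58	17.11/1.21	7.65/0.98	2.14/13.63	2.63/9.73
Hat1	0.56/0.99	0.09/1.32	12.93/24.06	49.03/30.61	46.29/21.08	26.19/20.45	29.7/11.00
Il15ra	1.42/0.59	0.07/0.54	2.25/11.67	0.64/5.29	2.21/12.29	4.80/14.33	1.58/20.32
Mapkbp1	0.03/0.18	0.13/2.25	96.09/4.23	25.15/33.87	22.48/30.68	123.55/25.01	263.85/15.93
Mga	0.68/0.24	0.34/0.68	4.24/12.63	4.57/28.72	5.14/27.86	8.89/78.35	7.84/62.23
Mkks	0.26/0.64	0.25/0.71	1.66/4.26	3.04/5.77	2.84/4.51	6.40/4.39	6.51/3.77
Mllt10	0.11/1.18	0.06/0.54	5.21/2.72	32.27/10.63	27.76/16.87	15.03/12.57	12.67/9.62
Mrps5	0.30/0.37	0.29/0.79	2.85/11.87	3.12/12.53	1.15/5.55	16.43/1.34	8.73/1.72
Necab3	3.74/0.72	0.49/0.20	3.72/10.21	2.23/38.12	6.28/36.48	11.85/20.21	3.01/23.07
Nr6a1	0.87/2.71	0.40/0.63	18.84/2.64	14.87/0.78	18.42/2.54	41.84/5.30	67.71/1.82
Ntng2	0.19/0.21	0.25/0.33	0.4/82.62	10.52/20.87	12.47/18.91	4.3/102.97	1.66/221.24
Nusap1	0.59/1.31	1.62/0.83	0.56/4.26	0.21/4.42	0.4/5.07	2.96/8.61	4.62/7.64
Olfr73	0.10/0.04	0.27/0.02	1.12/0.60	4.73/1.36	1.03/1.28	20.44/3.31	5.83/3.40
P2rx3	0.88/0.59	0.47/0.52	0.77/5.49	5.71/32.77	1.29/28.59	5.36/15.24	12.31/12.91
Pdhx	1.09/0.82	0.10/0.80	11.01/2.93	7.06/3.08	5.76/1.16	5.97/16.23	6.61/8.67
Phf20	0.77/3.35	0.87/0.37	0.88/2.17	5.00/1.11	3.20/3.81	1.03/7.36	0.67/1.62
Polr3f	0.83/1.25	0.21/0.69	10.77/16.44	10.86/12.56	14.35/15.82	15.73/35.52	7.5/57.87
Rae1	0.71/0.82	0.58/0.91	0.59/0.56	1.34/11.47	1.61/13.79	4.08/4.73	1.55/1.89
Rbm38	1.52/0.58	0.11/0.70	18.93/2.24	5.43/1.14	12.22/1.26	10.19/9.83	8.49/7.36
Scn1a	9.47/0.74	2.38/0.87	0.73/1.13	0.61/3.84	2.46/3.60	7.56/0.30	4.58/0.57
Slc12a5	4.24/0.92	0.59/2.15	2.84/0.38	3.26/0.04	3.41/0.21	4.93/2.38	5.08/3.83
Slc27a4	1.12/0.22	0.50/0.41	28.79/0.72	13.26/3.52	6.48/0.62	6.51/15.87	6.71/4.40
Slc34a3	0.33/1.15	0.38/0.69	10.17/0.48	10.98/4.46	19.71/0.89	20.08/4.17	17.79/9.87
Spata2	0.54/1.15	0.59/0.13	0.65/8.00	1.75/4.87	0.78/3.99	4.44/4.06	3.95/4.56
Sptlc3	0.42/0.74	0.31/1.10	26.19/5.08	2.31/7.18	13.32/8.05	179.36/10.23	250.13/8.40
Ss18l1	0.33/1.71	1.15/1.85	24.07/1.10	70.3/5.51	106.73/3.61	142.18/1.19	87.02/0.81
Surf6	0.14/2.78	0.03/0.71	0.36/0.10	1.56/1.44	0.98/0.59	4.86/3.33	5.65/2.12
Timm10	1.11/0.80	0.16/0.19	0.79/7.50	0.44/7.32	0.44/9.91	3.52/10.71	2.82/4.98
Trub2	0.41/1.52	0.58/1.33	0.34/0.72	1.71/1.45	0.55/1.77	4.38/4.31	1.61/1.68
Ttll9	0.06/2.02	0.03/0.34	13.59/16.46	4.75/4.47	8.44/10.41	63.39/8.51	39.11/7.1
Yme1l1	1.17/14.07	0.17/3.87	4.23/0.82	10.71/0.64	12.14/2.59	21.28/7.73	18.6/4.72
Arl6ip6	0.33/5.28	0.27/0.91	0.09/2.37	1.77/2.62	1.30/2.81	3.37/4.03	2.27/4.19
Cep152	0.58/2.53	1.26/5.71	1.95/0.32	28.84/1.17	18.63/0.56	5.03/3.14	2.63/3.27
Chd6	0.54/0.90	1.20/0.97	11.69/10.67	70.65/11.16	61.55/20.31	58.35/20.35	34.4/18.12
Ddb2	3.10/1.00	0.72/1.06	10.74/0.56	81.94/1.53	91.16/0.66	88.59/3.99	61.48/3.57
Dnmt3b	1.85/0.69	0.05/0.56	1.45/22.66	16.44/1.80	14.99/11.27	3.61/151.12	1.68/211.91
Dut	0.04/2.30	0.36/0.50	0.80/1.54	2.32/5.41	1.35/3.55	14.44/1.97	9.05/1.33
Emilin3	0.83/0.44	0.86/0.29	26.92/0.25	42.07/1.28	59.95/0.79	7.44/4.22	12.92/4.95
Entpd6	1.61/1.68	0.30/0.48	41.36/0.66	38.04/0.30	17.21/0.32	17.79/3.07	12.23/2.46
Mettl5	0.61/0.10	0.37/0.06	2.72/10.00	6.88/3.21	4.9/6.00	6.01/46.04	5.83/28.46
Myef2	0.58/0.69	0.11/0.33	0.74/1.38	0.91/3.04	2.12/3.57	4.87/9.78	3.94/8.22
Rif1	0.94/1.19	1.76/3.64	0.98/14.02	5.85/10.48	7.01/7.97	3.27/6.11	2.11/0.65
Sfmbt2	2.56/2.25	3.80/1.98	1.09/1.49	7.35/0.88	9.00/1.40	2.16/7.25	0.94/5.39
Gzf1	1/3.12	3.24/1.05	17.78/47.88	13.78/42.76	10.39/19.69	8.17/20.02	1.12/13.88
Pltp	9.94/3.83	2.17/3.01	189.9/16.60	7.67/31.99	8.30/21.33	110.19/13.79	96.66/22.44
Polr1b	1.83/1.59	1.33/1.47	7.01/5.03	6.45/10.25	3.06/18.41	10.71/37.36	8.50/46.25
Tasp1	2.19/7.78	1.12/8.13	1.96/2.59	15.91/2.34	12.47/4.49	20.97/8.59	8.31/9.50
Zbtb34	2.82/4.42	1.78/2.60	58.06/2.67	131.6/19.40	78.44/15.48	69.44/25.45	58.72/10.27
Zfp120	1.92/1.70	1.84/1.62	17.79/11.67	21.29/13.60	18.08/11.68	11.75/7.33	8.68/5.36
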