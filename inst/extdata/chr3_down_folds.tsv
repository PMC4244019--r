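gene	Fibroblast	Stem	ATII	CD8_T_BL	CD8_T_LL	Basal_cell	Duct_cell
1700027A23Rik	0.9/1.57	0.08/0.46	162.04/220.27	4.95/7.07	0.43/0.94	28.1/38.49	8.2/11.48
2810403A07Rik	0.81/1.11	0.7/0.99	0.47/0.72	3.33/4.07	4.16/5.04	1.31/1.7	0.96/1.3
4932438A13Rik	1.12/1.11	0.9/0.9	4.4/4.39	76.24/75.99	78.16/77.9	9.48/9.44	8.12/8.09
4933421E11Rik	1.61/2.74	0.22/0.74	0.3/0.87	5.03/7.64	4.6/7.02	2.41/3.89	0.14/0.64
A530020G20Rik	0.13/0.92	0.02/0.73	6.3/11.39	1.91/3.94	2.91/5.64	2.4/4.77	1.14/2.63
Acadm	5.66/5.92	0.22/0.27	4.5/4.72	6.8/7.1	4.87/5.09	6.25/6.53	5.1/5.33
Adh6a	0.46/0.67	0.44/0.65	5.68/6.63	8.32/9.65	11.57/13.37	50.97/58.39	25.27/29.03
Ahcyl1	0.62/0.88	0.14/0.32	1.5/1.91	1.14/1.49	0.51/0.76	2.4/2.95	1.9/2.38
Alx3	1.08/1.53	1.35/1.87	0.45/0.77	0.95/1.38	5.61/7.05	0.82/1.22	1.64/2.21
Atp11b	0.44/0.93	0.99/1.66	2.2/3.29	28.57/38.63	22.24/30.15	10.08/13.85	15.11/20.59
Car3	0.25/0.29	0.04/0.07	3.72/3.87	4.07/4.23	6.87/7.12	40.74/42.05	22.72/23.47
Clcc1	1.62/2.56	0.03/0.39	0.08/0.47	0.81/1.45	0.7/1.31	3.29/4.83	3.25/4.77
Cryz	3.65/6.13	3.67/6.15	0.91/1.92	0.17/0.79	0/0.53	0.51/1.32	2.14/3.8
Ctso	0.22/0.15	1.18/1.05	151.36/142.4	336.91/317.03	271.25/255.24	245.94/231.42	92.66/87.15
Gnat2	1.35/1.57	0.19/0.3	1.09/1.29	2.4/2.72	4.24/4.73	8.71/9.63	1.89/2.17
Gpsm2	1.89/2.66	1.39/2.03	0.36/0.72	3.42/4.59	5.15/6.78	14.01/17.99	18.95/24.24
Hax1	0.16/0.6	0.66/1.3	1.25/2.1	0.9/1.62	0.94/1.68	0.6/1.21	0.84/1.54
Hltf	0.31/0.45	0.45/0.61	3.26/3.75	18.55/20.78	18.24/20.44	7.82/8.83	3.57/4.09
Hps3	1.39/1.42	0.56/0.58	0.8/0.82	8.25/8.37	6.09/6.18	2.97/3.02	0.26/0.27
Ints3	0.83/0.94	0.23/0.3	27.92/29.65	13.8/14.68	6.12/6.54	23.06/24.5	26.27/27.9
Isg20l2	0.09/0.62	0.06/0.57	2.61/4.35	4.77/7.55	3.23/5.27	5.9/9.22	6.17/9.62
Lass2	0.06/0.12	0.01/0.07	5.54/5.9	2.13/2.3	1.64/1.79	1.12/1.23	0.41/0.49
Lrrc40	0.4/0.16	0.42/0.18	102.03/84.89	256.01/213.26	257.71/214.68	537.73/448.12	349.78/291.43
Lrrcc1	0.1/0.63	0.19/0.77	0.6/1.37	2.23/3.8	1.26/2.35	5.2/8.21	2.45/4.13
Mfsd8	0.71/0.3	0.45/0.11	11.71/8.67	24.91/18.72	19.66/14.72	32.59/24.56	33.42/25.19
Mrpl24	0.64/1.57	0.06/0.66	1.1/2.27	3.11/5.41	1.92/3.56	1.85/3.45	1.82/3.41
Mrpl9	0.29/0.47	0.44/0.64	3.16/3.73	7.18/8.3	5.33/6.19	8.23/9.48	7.87/9.08
Ndufb5	1/1.86	0.01/0.44	2.17/3.55	2.34/3.79	0.88/1.69	2.78/4.42	2.95/4.66
Odf2l	1.26/1.48	0.17/0.29	5.61/6.26	11.82/13.08	7.95/8.83	44.13/48.56	37.95/41.78
Papss1	1.13/1.25	0.44/0.52	2.44/2.62	1.53/1.66	0.28/0.34	1.73/1.88	1.64/1.78
Pgrmc2	1.11/1.55	0.08/0.31	4.75/5.96	1.45/1.97	2/2.62	29.73/36.17	15.37/18.8
Plk4	0.46/0.88	0.71/1.2	2.33/3.29	11.64/15.29	12.8/16.79	7.3/9.69	12.53/16.43
Prpf38b	1.18/0.93	0.68/0.49	11.25/9.81	50/44	66.2/58.3	44.75/39.37	34.78/30.58
Rabggtb	0.81/0.52	1.09/0.75	8.12/6.64	53.93/45.01	57.59/48.07	37.82/31.52	48.92/40.81
Rapgef2	0.29/0.68	0.63/1.11	2.8/3.92	10.47/13.85	8.15/10.86	0.24/0.6	0.61/1.09
Rps4x	0.11/0.67	0.62/1.45	0.39/1.1	0.85/1.79	1.99/3.51	0.67/1.53	0.54/1.32
Sars	3.16/4.85	1.32/2.27	1.03/1.86	0.4/0.98	0.09/0.54	0.41/0.99	0.3/0.83
Setdb1	0.25/0.87	0.6/1.39	0.03/0.55	1.29/2.42	1.07/2.1	2.73/4.58	1.8/3.19
Siah2	1.29/1.68	1.79/2.27	3.92/4.77	0.21/0.42	0.87/1.19	3.28/4.02	3.03/3.72
Slc33a1	0.75/0.58	0.72/0.55	5.56/4.91	2.19/1.87	1.75/1.48	3.02/2.62	0.75/0.58
Smc4	0.07/0.85	0.89/2.26	0.12/0.94	14.46/25.7	14.77/26.25	2.22/4.56	6.28/11.58
Sohlh2	0.02/0.11	0.08/0.17	1.69/1.93	0.91/1.07	1.86/2.11	1.58/1.8	1.85/2.1
Spata5	0.06/0.88	0.21/1.16	0.19/1.12	0.32/1.36	0.4/1.49	1.15/2.83	1.51/3.47
Syt6	0.23/0.6	0.21/0.57	0.15/0.5	0.55/1.02	0.43/0.87	1.27/1.96	0.29/0.69
Tbl1xr1	2.36/1.6	0.89/0.47	2.59/1.79	4.02/2.9	3.66/2.61	16.91/12.89	13.56/10.29
Txnip	0.77/0.21	1.35/0.6	54.04/36.58	107.86/73.33	65.79/44.6	36.39/24.53	26.15/17.53
Ubqln4	0.18/0.58	0.21/0.63	11.94/16.36	5.82/8.15	2.66/3.91	28.73/38.87	40.6/54.79
Wdr77	0.14/0.7	0.97/1.92	3.67/5.93	1.52/2.74	0.79/1.66	2.28/3.88	2.96/4.88
Ythdf3	0.22/0.54	0.64/1.07	3.08/4.17	6.8/8.87	6.44/8.41	3.68/4.92	3/4.06
Zzz3	0.1/0.64	0.73/1.58	0.1/0.64	3.91/6.33	3.67/5.96	1.29/2.42	0.6/1.39
1700013F07Rik	6.5/7.08	1.64/1.84	34.73/37.52	2.1/2.34	7.8/8.48	29.96/32.38	47.84/51.65
Amy1	2.81/3.86	8.06/10.55	9.44/12.32	7.37/9.67	14.79/19.13	31.07/39.88	24.64/31.68
Anp32e	8.69/11.5	2.79/3.89	121.76/157.32	245.2/316.52	243.57/314.42	356.1/459.55	464.63/599.52
Dnase2b	2.08/2.96	1.85/2.67	1.08/1.68	1.08/1.67	9.48/12.48	10.22/13.44	6.68/8.87
Fmo5	3.8/6	3.36/5.35	3.52/5.58	4.08/6.4	1.75/3.01	21.33/31.55	5.4/8.33
Pde5a	4.09/2.99	3.94/2.87	4.58/3.37	39.25/30.54	12.26/9.39	44.99/35.04	15.96/12.29
Phf17	1.24/1.76	3.48/4.52	1.04/1.52	3.4/4.42	3.67/4.75	11.3/14.14	4.48/5.75
Rwdd3	2.98/4.43	2.52/3.8	2.98/4.43	14.07/19.53	10.16/14.21	28.88/39.73	8.77/12.31
Trim33	1.93/5.56	1.06/3.62	4.2/10.64	26.9/61.48	17.78/41.07	3.1/8.17	2.63/7.13
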