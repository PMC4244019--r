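gene	Fibroblast	Stem	ATII	CD8_T_BL	CD8_T_LL	Basal_cell	Duct_cell
Agl	-0.31/-0.25	-0.42/-0.37	-0.64/-0.6	-0.54/-0.5	-0.81/-0.79	-0.63/-0.6	-0.79/-0.77
Ecm1	-0.96/-0.96	-0.9/-0.9	-0.91/-0.91	-0.96/-0.96	-0.85/-0.85	-0.48/-0.47	-0.24/-0.23
Golim4	-0.65/-0.63	-0.24/-0.2	-0.86/-0.85	-0.8/-0.79	-0.86/-0.86	-0.65/-0.63	-0.48/-0.45
Kcnab1	-0.94/-0.95	-0.39/-0.54	-0.73/-0.8	-0.62/-0.71	-0.9/-0.93	-0.24/-0.42	-0.65/-0.73
Lce1a2	-0.16/-0.3	-0.41/-0.52	-0.01/-0.18	-0.03/-0.2	-0.24/-0.37	-0.83/-0.86	-0.93/-0.94
Nexn	-0.59/-0.47	-0.3/-0.08	-0.82/-0.76	-0.9/-0.87	-0.96/-0.95	-0.64/-0.52	-0.78/-0.71
Pde4dip	-0.65/-0.69	-0.52/-0.58	-0.19/-0.29	-0.11/-0.22	-0.4/-0.47	-0.71/-0.75	-0.68/-0.72
Plekho1	-0.07/-0.3	-0.8/-0.85	-0.8/-0.85	-0.85/-0.89	-0.97/-0.98	-0.95/-0.97	-0.98/-0.99
Psrc1	-0.8/-0.7	-0.78/-0.67	-0.81/-0.73	-0.72/-0.59	-0.62/-0.45	-0.32/0	-0.38/-0.1
Rhoc	-0.57/-0.52	-0.5/-0.43	-0.85/-0.83	-1/-1	-0.92/-0.91	-0.6/-0.55	-0.73/-0.69
Rit1	-0.54/-0.53	-0.66/-0.65	-0.58/-0.57	-0.69/-0.68	-0.66/-0.65	-0.25/-0.22	-0.57/-0.55
Scamp3	-0.34/-0.34	-0.55/-0.55	-0.79/-0.79	-0.61/-0.61	-0.72/-0.72	-0.82/-0.82	-0.83/-0.83
Sec22b	-0.41/-0.08	-0.5/-0.23	-0.49/-0.21	-0.55/-0.3	-0.63/-0.43	-0.56/-0.32	-0.65/-0.46
Sh3glb1	-0.73/-0.68	-0.62/-0.54	-0.81/-0.77	-0.79/-0.75	-0.8/-0.76	-0.69/-0.62	-0.7/-0.63
Tm4sf1	-1/-1	-0.6/-0.67	-0.85/-0.88	-1/-1	-1/-1	-0.99/-0.99	-0.99/-0.99
Csf1	-0.71/-0.65	-0.73/-0.68	-0.93/-0.92	-0.98/-0.98	-0.98/-0.97	-0.91/-0.9	-0.92/-0.91
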