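gene	Fibroblast	Stem	ATII	CD8_T_BL	CD8_T_LL	Basal_cell	Duct_cell
1110008F13Rik	-0.41/-0.18	-0.46/-0.25	-0.73/-0.72	-0.79/-0.80	-0.85/-0.85	-0.91/-0.91	-0.91/-0.92
2310003F16Rik	-0.40/-0.04	-0.49/-0.19	-0.97/-0.97	-0.52/-0.46	-0.56/-0.50	-0.82/-0.80	-0.86/-0.84
2900064A13Rik	-0.13/-0.21	-0.41/-0.46	-0.37/-0.58	-0.29/-0.54	-0.30/-0.54	-0.24/-0.51	-0.19/-0.47
Abl1	-0.75/-0.67	-0.43/-0.23	-0.76/-0.76	-0.29/-0.32	-0.70/-0.71	-0.82/-0.83	-0.89/-0.90
Ass1	-0.44/-0.34	-0.96/-0.95	-0.82/-0.84	-0.94/-0.95	-0.80/-0.83	-0.90/-0.92	-0.80/-0.84
Commd3	-0.63/-0.13	-0.63/-0.54	-0.56/-0.62	-0.78/-0.59	-0.76/-0.60	-0.13/-0.34	-0.24/-0.65
Commd7	-0.29/-0.56	-0.62/-0.91	-0.58/-0.49	-0.53/-0.99	-0.54/-0.99	-0.24/-0.87	-0.60/-0.89
Creb3l1	-0.65/-0.66	-0.93/-0.44	-0.46/-0.35	-0.99/-0.18	-0.99/-0.52	-0.86/-0.25	-0.88/-0.29
Dlgap4	-0.79/-0.98	-0.65/-0.96	-0.44/-0.77	-0.28/-1.00	-0.58/-0.96	-0.34/-0.37	-0.38/-0.71
Edf1	-0.44/-0.17	-0.40/-0.08	-0.51/-0.73	-0.78/-0.76	-0.81/-0.61	-0.26/-0.28	-0.26/-0.66
Id1	-0.98/-0.70	-0.97/-0.03	-0.74/-0.20	-0.99/-0.50	-0.95/-0.45	-0.27/-0.63	-0.66/-0.59
Manbal	-0.49/-0.51	-0.43/-0.43	-0.77/-0.34	-0.79/-0.19	-0.66/-0.19	-0.37/-0.20	-0.71/-0.25
Mocs3	-0.81/-0.53	-0.38/-0.02	-0.30/-0.90	-0.55/-0.95	-0.51/-0.95	-0.67/-0.55	-0.63/-0.57
Psmc3	-0.64/-0.46	-0.58/-0.20	-0.34/-0.29	-0.17/-0.58	-0.18/-0.36	-0.18/-0.67	-0.23/-0.93
Sdccag3	-0.44/-0.46	-0.48/-0.60	-0.76/-0.37	-0.77/-0.98	-0.74/-0.94	-0.73/-0.45	-0.67/-0.18
Slc39a13	-0.51/-0.59	-0.28/-0.77	-0.13/-0.42	-0.46/-0.73	-0.20/-0.75	-0.58/-0.72	-0.91/-0.80
Snai1	-0.84/-0.26	-0.37/-0.15	-0.92/-0.67	-0.93/-0.74	-0.95/-0.58	-0.95/-0.40	-0.97/-0.59
Spc25	-0.41/-0.37	-0.24/-0.40	-0.79/-0.91	-0.61/-0.91	-0.41/-0.91	-0.19/-0.58	-0.07/-0.85
Tubb2c	-0.73/-0.59	-0.84/-0.48	-0.47/-0.40	-0.74/-0.90	-0.77/-0.89	-0.73/-0.57	-0.81/-0.74
Srxn1	-0.49/-0.68	-0.71/-0.30	-0.32/-0.86	-0.96/-0.85	-0.93/-0.83	-0.69/-0.86	-0.41/-0.93
Dbndd2	-0.61/-1.00	-0.66/-0.98	-0.90/-0.73	-0.96/-0.96	-0.95/-0.96	-0.83/-0.87	-0.81/-0.90
Fbn1	-0.95/-0.98	-0.84/-0.53	-0.89/-0.84	-0.95/-0.82	-0.95/-0.84	-0.66/-0.87	-0.89/-0.76
Tfpi	-0.60/-0.72	-0.94/-0.58	-0.85/-0.85	-0.66/-0.95	-0.73/-0.96	-0.84/-0.78	-0.82/-0.86
Ak1	-0.80/-0.74	-0.84/-0.96	-0.69/-0.93	-1.00/-0.85	-0.97/-0.87	-0.94/-0.93	-0.97/-0.92
Myl9	-1.00/-0.96	-0.92/-0.91	-0.98/-0.92	-1.00/-0.96	-1.00/-0.98	-0.98/-0.88	-1.00/-0.94
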