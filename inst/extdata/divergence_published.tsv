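contig	pair	n_genes	mean_ks	sd_ks	mean_mya	sd_mya
A	B_vs_A	15	0.18	0.07	6.073	2.18
A	B_vs_C	15	0.19	0.06	6.60	2.04
A	B_vs_At	15	0.42	0.10	14.30	3.28
A	A_vs_C	15	0.09	0.05	3.22	1.68
A	A_vs_At	15	0.41	0.09	13.68	2.91
A	C_vs_At	15	0.41	0.09	13.96	3.16
B	B_vs_A	25	0.20	0.07	6.92	2.25
B	B_vs_C	25	0.22	0.06	7.36	2.10
B	B_vs_At	25	0.42	0.09	14.20	2.99
B	A_vs_C	25	0.09	0.05	3.20	1.65
B	A_vs_At	25	0.43	0.10	14.44	3.24
B	C_vs_At	25	0.45	0.10	15.04	3.31
C	B_vs_A	16	0.18	0.06	6.30	2.01
C	B_vs_C	16	0.18	0.07	6.06	2.41
C	B_vs_At	16	0.45	0.13	15.07	4.45
C	A_vs_C	16	0.10	0.06	3.47	1.85
C	A_vs_At	16	0.43	0.10	14.54	3.41
C	C_vs_At	16	0.43	0.11	14.39	3.61
D	B_vs_A	28	0.20	0.11	6.81	3.67
D	B_vs_C	28	0.19	0.09	6.34	2.96
D	B_vs_At	28	0.50	0.14	16.69	4.69
D	A_vs_C	28	0.10	0.06	3.59	1.85
D	A_vs_At	28	0.52	0.18	17.40	5.86
D	C_vs_At	28	0.50	0.18	16.99	5.99
E	B_vs_A	7	0.15	0.04	5.17	1.46
E	B_vs_C	7	0.14	0.04	4.91	1.38
E	B_vs_At	7	0.48	0.19	16.03	6.44
E	A_vs_C	7	0.08	0.05	2.97	1.51
E	A_vs_At	7	0.46	0.18	15.47	6.12
E	C_vs_At	7	0.46	0.18	15.59	6.12
F	B_vs_A	41	0.19	0.05	6.46	1.91
F	B_vs_C	41	0.18	0.06	6.32	1.98
F	B_vs_At	41	0.47	0.14	15.93	4.70
F	A_vs_C	41	0.08	0.03	2.76	1.11
F	A_vs_At	41	0.48	0.14	16.10	4.64
F	C_vs_At	41	0.47	0.14	15.83	4.65
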