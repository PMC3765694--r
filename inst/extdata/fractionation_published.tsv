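contig	genome	size_bp	n_te	retained_exons	ref_exons	retained_genic	ref_genes	predicted_genes	n_ab_initio	printed_exon_pct	printed_genic_pct	printed_predicted_pct	printed_density
A	A	311929	3	190	388	46	67	29	72	48.97	68.66	43.28	4332.35
A	B	258940	5	207	388	44	67	35	71	53.35	65.67	52.24	3647.04
A	C	586573	32	184	388	43	67	28	159	47.42	64.18	41.79	3689.14
B	A	365330	14	270	496	55	89	41	82	54.44	61.80	46.07	4455.24
B	B	258875	1	288	496	62	89	46	64	58.06	69.66	51.69	4044.92
B	C	828528	42	287	496	55	89	40	189	57.86	61.80	44.94	4383.75
C	A	154252	0	174	243	34	42	25	32	71.60	80.95	59.52	4820.38
C	B	175460	2	163	243	36	42	31	38	67.08	85.71	73.81	4617.37
C	C	398219	14	181	243	34	42	29	102	74.49	80.95	69.05	3904.11
D	A	278470	0	243	456	64	88	42	66	53.29	72.73	47.73	4219.24
D	B	386079	4	336	456	73	88	48	115	73.68	82.95	54.55	3357.21
D	C	362518	4	240	456	64	88	45	99	52.63	72.73	51.14	3661.80
E	A	132246	8	92	222	17	34	14	38	41.44	50.00	41.18	3480.16
E	B	159548	7	85	222	15	34	14	42	38.29	44.12	41.18	3798.76
E	C	234259	10	82	222	16	34	13	70	36.94	47.06	38.24	3346.56
F	A	510517	12	366	503	80	96	65	121	72.76	83.33	67.71	4219.15
F	B	450974	8	371	503	84	96	70	113	73.76	87.50	72.92	3990.92
F	C	543877	37	363	503	86	96	62	159	72.17	89.58	64.58	3420.61
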