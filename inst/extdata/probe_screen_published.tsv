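probe	n_positive	n_loci	printed_redundancy
At4g17260	28	1	28.0
At4g17300	37	1	37.0
At4g17340	77	1	77.0
At4g17350	54	2	27.0
At4g17380	17	2	8.5
At4g17410	43	2	21.5
At4g17440	83	1	83.0
At4g17460	51	3	17.0
At4g17480	35	4	8.7
At4g17500	40	1	40.0
At4g17570	58	2	29.0
At4g17600	107	2	53.5
At4g17650	21	1	21.0
At4g17700	10	3	3.3
At4g17730	67	1	67.0
At4g17760	19	2	9.5
At4g17800	85	3	28.3
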