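dataset	type	delta_e	pct
18s	5	0.00	17.2
18s	3	0.58	15.0
18s	4	0.84	14.1
18s	6	1.07	13.3
18s	1	1.89	10.9
18s	8	1.90	10.9
18s	7	2.06	10.5
18s	2	3.05	8.2
18d	6	0.00	20.1
18d	4	0.37	18.3
18d	3	0.90	16.1
18d	8	1.90	12.6
18d	5	3.03	9.6
18d	1	3.61	8.3
18d	7	3.66	8.2
18d	2	4.54	6.7
18s-complexed	1	0.00	28.5
18s-complexed	8	0.30	26.5
18s-complexed	7	0.54	25.1
18s-complexed	2	1.47	19.9
18d-complexed	8	0.00	50.1
18d-complexed	7	4.04	18.8
18d-complexed	1	4.30	17.6
18d-complexed	2	5.39	13.5
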