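trait	n	mean	sd	min	max	cv_percent	sigma_a2	sigma_e2	sigma_p2	h2	h2_se
BW	6022	44.96	5.38	29	61	11.97	10.165	14.150	24.315	0.42	0.03
YW	3996	418.21	68.37	264.94	608.65	16.36	444.650	1352.400	1797.050	0.24	0.03
BYADG	3996	1.03	0.19	0.6	1.54	18.45	0.003	0.010	0.013	0.23	0.02
18MW	3137	587.41	109.36	376.84	905.24	18.61	1193.400	1598.000	2791.400	0.43	0.03
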