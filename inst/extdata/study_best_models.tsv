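mode	subject	algorithm	config	tpr_pct	tpr_sd	fp_per_min	fp_sd	acc_pct	acc_sd
offline	1	D	4	63.8	24.5	1.69	2.18	89.1	13.7
offline	2	E	6	50.0	27.3	0.19	0.75	93.8	25.0
offline	3	D	1	71.3	29.2	2.25	2.57	78.6	26.9
offline	4	C	3	67.5	20.5	2.44	2.50	83.7	16.8
offline	5	A	1	82.5	21.8	3.56	4.55	82.8	20.8
pseudo-online	1	D	4	83.3	15.1	10.3	6.33	25.1	11.7
pseudo-online	2	B	8	76.7	23.4	0.08	0.20	96.7	8.16
pseudo-online	3	D	2	86.7	20.7	6.83	3.29	32.1	9.33
pseudo-online	4	C	2	76.7	15.1	3.74	2.20	81.8	15.9
pseudo-online	5	E	4	60.0	17.9	3.73	1.82	39.9	14.7
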