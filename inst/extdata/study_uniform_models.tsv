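procedure	subject	algorithm	config	tpr_pct	tpr_sd	fp_per_min	fp_sd	acc_pct	acc_sd
uniform-algorithm	1	D	4	83.3	15.1	10.3	6.33	25.1	11.7
uniform-algorithm	2	D	4	66.7	16.3	0.26	0.45	90.0	16.7
uniform-algorithm	3	D	2	86.7	20.7	6.83	3.29	32.1	9.33
uniform-algorithm	4	D	6	86.7	16.3	3.76	2.10	47.0	9.38
uniform-algorithm	5	D	1	56.7	23.4	3.83	1.07	35.5	9.63
uniform-all	1	D	4	83.3	15.1	10.3	6.33	25.1	11.7
uniform-all	2	D	4	66.7	16.3	0.27	0.45	90.0	16.7
uniform-all	3	D	4	96.7	8.16	10.1	4.06	26.3	7.89
uniform-all	4	D	4	93.3	10.3	9.50	2.51	27.5	7.85
uniform-all	5	D	4	70.0	21.0	12.6	3.32	17.2	3.17
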