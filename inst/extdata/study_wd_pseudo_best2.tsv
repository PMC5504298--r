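subject	algorithm	config	wd
1	C	1	0.24
1	C	2	0.22
1	C	3	0.30
1	C	4	0.29
1	C	5	0.22
1	C	6	0.16
1	C	7	0.17
1	C	8	0.23
1	D	1	-0.04
1	D	2	0.18
1	D	3	0.15
1	D	4	0.31
1	D	5	0.11
1	D	6	0.27
1	D	7	0.14
1	D	8	0.06
2	B	1	0.81
2	B	2	0.69
2	B	3	0.61
2	B	4	0.53
2	B	5	0.60
2	B	6	0.73
2	B	7	0.86
2	B	8	0.89
2	E	1	0.81
2	E	2	0.77
2	E	3	0.84
2	E	4	0.85
2	E	5	0.82
2	E	6	0.77
2	E	7	0.84
2	E	8	0.76
3	C	1	0.42
3	C	2	0.33
3	C	3	0.41
3	C	4	0.38
3	C	5	0.36
3	C	6	0.37
3	C	7	0.28
3	C	8	0.35
3	D	1	0.37
3	D	2	0.43
3	D	3	0.29
3	D	4	0.38
3	D	5	0.29
3	D	6	0.33
3	D	7	0.31
3	D	8	0.35
4	C	1	0.74
4	C	2	0.74
4	C	3	0.67
4	C	4	0.67
4	C	5	0.67
4	C	6	0.68
4	C	7	0.71
4	C	8	0.70
4	D	1	0.47
4	D	2	0.48
4	D	3	0.51
4	D	4	0.38
4	D	5	0.38
4	D	6	0.57
4	D	7	0.58
4	D	8	0.57
5	A	1	0.34
5	A	2	0.35
5	A	3	0.32
5	A	4	0.23
5	A	5	0.35
5	A	6	0.35
5	A	7	0.29
5	A	8	0.28
5	E	1	0.36
5	E	2	0.42
5	E	3	0.24
5	E	4	0.42
5	E	5	0.27
5	E	6	0.23
5	E	7	0.24
5	E	8	0.32
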