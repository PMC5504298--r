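subject	window	config	A	B	C	D	E
1	2s	1	0.11	0.09	0.47	0.08	0.40
1	2s	2	0.21	0.02	0.26	0.17	0.22
1	2s	3	0.07	0.26	0.40	0.24	0.26
1	2s	4	0.04	0.01	0.24	0.39	0.14
1	2s	5	0.05	0.19	0.30	0.23	0.39
1	2s	6	0.02	0.06	0.04	0.14	0.18
1	2s	7	0.33	0.22	0.10	0.16	0.17
1	2s	8	0.12	0.16	0.31	0.21	0.16
1	4s	1	0.28	0.16	0.60	0.51	0.27
1	4s	2	0.32	0.02	0.41	0.53	0.47
1	4s	3	0.17	0.27	0.61	0.50	0.39
1	4s	4	0.22	-0.05	0.61	0.68	0.57
1	4s	5	0.10	0.07	0.50	0.33	0.35
1	4s	6	0.18	0.07	0.28	0.43	-0.01
1	4s	7	0.14	0.12	0.33	0.38	0.13
1	4s	8	0.24	-0.12	0.56	0.52	0.36
2	2s	1	-0.13	0.12	-0.14	-0.07	0.29
2	2s	2	0.03	0.15	-0.07	0.04	0.41
2	2s	3	-0.21	0.11	-0.23	-0.04	0.16
2	2s	4	-0.02	0.12	0.09	-0.11	0.34
2	2s	5	-0.09	0.16	-0.07	0.09	0.21
2	2s	6	-0.14	0.34	-0.11	-0.15	0.41
2	2s	7	-0.16	0.25	-0.27	-0.09	0.36
2	2s	8	-0.17	0.41	-0.09	-0.12	0.35
2	4s	1	0.36	0.68	0.62	0.74	0.72
2	4s	2	0.07	0.59	0.39	0.70	0.70
2	4s	3	0.27	0.71	0.57	0.69	0.67
2	4s	4	0.32	0.48	0.25	0.64	0.71
2	4s	5	0.28	0.68	0.64	0.76	0.74
2	4s	6	-0.16	0.56	0.58	0.74	0.75
2	4s	7	0.27	0.66	0.57	0.72	0.76
2	4s	8	0.29	0.68	0.56	0.75	0.76
3	2s	1	0.25	0.15	0.20	0.21	0.28
3	2s	2	0.00	-0.01	0.17	-0.01	0.31
3	2s	3	0.15	0.19	0.29	0.07	0.26
3	2s	4	0.17	0.37	0.19	0.21	0.23
3	2s	5	0.04	0.26	0.14	0.07	0.30
3	2s	6	0.02	0.10	0.20	0.19	0.15
3	2s	7	0.06	0.32	0.20	0.10	0.23
3	2s	8	-0.15	0.19	0.19	-0.05	0.12
3	4s	1	0.47	0.20	0.51	0.61	0.41
3	4s	2	0.30	-0.12	0.51	0.57	0.40
3	4s	3	0.36	0.13	0.57	0.52	0.41
3	4s	4	0.30	0.11	0.57	0.55	0.50
3	4s	5	0.31	0.32	0.58	0.46	0.46
3	4s	6	0.28	0.07	0.58	0.59	0.27
3	4s	7	0.21	0.06	0.44	0.57	0.35
3	4s	8	0.29	0.11	0.53	0.57	0.44
4	2s	1	0.14	0.02	0.47	0.26	0.22
4	2s	2	-0.03	0.12	0.26	0.32	0.08
4	2s	3	0.10	-0.01	0.40	0.42	0.29
4	2s	4	0.08	0.14	0.24	0.22	0.18
4	2s	5	0.13	0.16	0.30	0.34	0.20
4	2s	6	0.12	0.03	0.04	0.21	0.13
4	2s	7	0.12	0.24	0.10	0.34	0.16
4	2s	8	0.06	0.13	0.01	0.43	0.20
4	4s	1	0.35	0.22	0.60	0.61	0.50
4	4s	2	-0.01	0.16	0.41	0.48	0.22
4	4s	3	0.25	0.27	0.61	0.59	0.53
4	4s	4	0.14	-0.12	0.61	0.50	0.30
4	4s	5	0.16	0.21	0.50	0.53	0.38
4	4s	6	0.10	0.19	0.28	0.57	0.33
4	4s	7	0.21	0.12	0.33	0.57	0.49
4	4s	8	0.14	0.21	0.36	0.61	0.40
5	2s	1	0.17	0.18	0.25	0.27	0.10
5	2s	2	0.11	0.02	0.07	0.15	0.08
5	2s	3	0.06	0.10	0.17	0.24	0.12
5	2s	4	-0.02	-0.08	0.01	-0.06	-0.02
5	2s	5	0.26	0.21	0.11	0.13	0.05
5	2s	6	0.24	0.03	0.26	0.27	0.09
5	2s	7	0.33	0.00	0.26	0.20	0.03
5	2s	8	0.15	-0.11	0.20	0.26	0.20
5	4s	1	0.59	0.25	0.58	0.54	0.52
5	4s	2	0.53	0.15	0.32	0.56	0.40
5	4s	3	0.43	0.16	0.33	0.53	0.31
5	4s	4	0.48	0.23	0.10	0.24	0.31
5	4s	5	0.49	0.11	0.32	0.47	0.42
5	4s	6	0.42	0.28	0.45	0.50	0.46
5	4s	7	0.54	0.09	0.55	0.53	0.37
5	4s	8	0.50	0.32	0.47	0.55	0.41
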