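event	copies	n_positive	n_total	mean_ct	sd_ct	rsd_percent
GTS-40-3-2	80	10	10	34.63	0.46	1.32
GTS-40-3-2	50	10	10	35.11	0.31	0.89
GTS-40-3-2	40	10	10	35.51	0.47	1.33
GTS-40-3-2	20	10	10	36.28	0.31	0.86
GTS-40-3-2	10	10	10	37.33	0.49	1.31
GTS-40-3-2	5	8	10
GTS-40-3-2	1	4	12
MON1445	80	10	10	33.27	0.24	0.73
MON1445	50	10	10	34.47	0.26	0.75
MON1445	40	10	10	34.96	0.27	0.78
MON1445	20	10	10	35.69	0.48	1.33
MON1445	10	10	10	36.64	0.49	1.32
MON1445	5	9	10
MON1445	1	4	12
OXY235	80	10	10	33.34	0.26	0.79
OXY235	50	10	10	34.47	0.26	0.75
OXY235	40	10	10	35.16	0.47	1.33
OXY235	20	10	10	36.80	0.39	1.07
OXY235	10	10	10	38.29	0.58	1.52
OXY235	5	2	10
OXY235	1	2	10
KMD	80	10	10	33.28	0.65	1.94
KMD	50	10	10	34.40	0.37	1.08
KMD	40	10	10	35.09	0.32	0.93
KMD	20	10	10	36.50	0.49	1.34
KMD	10	10	10	37.15	0.80	2.14
KMD	5	3	10
KMD	1	5	10
TC1507	80	10	10	32.40	0.38	1.18
TC1507	50	10	10	33.31	0.36	1.08
TC1507	40	10	10	34.03	0.44	1.30
TC1507	20	10	10	35.73	0.40	1.13
TC1507	10	10	10	36.17	0.57	1.59
TC1507	5	2	10
TC1507	1	5	12
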