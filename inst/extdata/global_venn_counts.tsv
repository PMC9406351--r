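dose_gy	timepoint	unique	union	common
1	2h	37	1665	0
1	d4	16	1665	0
1	d7	19	1665	0
1	d21	8	1665	0
1	d28	5	1665	0
3	2h	4	1665	0
3	d4	6	1665	0
3	d7	2	1665	0
3	d21	28	1665	0
3	d28	32	1665	0
6	2h	4	1665	0
6	d4	43	1665	0
6	d7	55	1665	0
6	d21	35	1665	0
6	d28	18	1665	0
20	2h	34	1665	0
20	d4	50	1665	0
20	d7	58	1665	0
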