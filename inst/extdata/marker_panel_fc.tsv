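gene	1|2h	1|d4	1|d7	3|2h	3|d4	3|d7	6|2h	6|d4	6|d7	20|2h	20|d4	20|d7
AADAC	2.41	3.89	2.86	2.86	2.49	2.31	2.89	2.43	6.31	-7.09	-7.44	-8.54
ELOVL4	2.09	3.48	2.73	2.10	2.57	2.32	2.32	3.05	5.50	-7.36	-5.93	-6.79
SEC14L4	2.58	3.46	3.11	2.38	2.18	2.17	2.72	2.88	6.51	-6.28	-6.46	-6.50
SLURP1	2.29	3.33	3.01	2.07	3.10	2.31	2.21	2.95	4.33	-3.08	-2.52	-3.29
TMPRSS4	3.01	4.94	2.39	3.30	3.07	3.11	2.08	2.05	3.35	-2.67	-2.69	-2.77
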