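timepoint	union	common	u_1gy	u_3gy	u_6gy	u_20gy
2h	1096	17	83	14	36	702
d4	1079	24	78	15	107	620
d7	1121	16	34	7	179	666
d21	314	5	47	76	118	NA
d28	322	19	21	66	112	NA
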