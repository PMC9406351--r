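dose_gy	union	common	u_2h	u_d4	u_d7	u_d21	u_d28
1	619	1	125	101	26	51	62
3	411	0	61	35	20	99	82
6	765	4	47	84	173	52	88
20	1038	609	57	80	89	NA	NA
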