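gene	fc
TRIM63	4.607
MYLK4	4.488
MSTN	3.841
KRT31	-3.736
AADAC	2.41
ELOVL4	2.09
SEC14L4	2.58
SLURP1	2.29
TMPRSS4	3.01
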