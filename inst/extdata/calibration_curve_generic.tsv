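hu	density
-1000	0.001
-700	0.302
-90	0.950
0	1.000
55	1.055
120	1.090
500	1.280
1000	1.560
3000	2.700
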