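id	circ_a	circ_b	circ_c	circ_d	circ_e
circ_a	1	0.6875	0.125	0.003697863716482932	0.4375
circ_b	0.6875	1	0.125	0.014995576820477717	0.45833333333333331
circ_c	0.125	0.125	1	0.24659696394160649	0.1875
circ_d	0.003697863716482932	0.014995576820477717	0.24659696394160649	1	0.24659696394160649
circ_e	0.4375	0.45833333333333331	0.1875	0.24659696394160649	0.83333333333333326
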