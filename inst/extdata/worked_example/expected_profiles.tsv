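gene	O1	O2	O3	O4	O5	O6
O1_b1	1	1	1	1	1	1
O1_b2	1	1	0	0	0	0
O1_b3	1	0	1	1	0	0
O1_b4	1	0	0	0	0	0
O1_b5	1	1	1	1	1	0
O1_m1a	1	1	1	0	0	1
O1_m1b	1	1	1	0	0	1
O1_m1c	1	1	1	0	0	1
O1_m1d	1	1	1	0	0	1
O1_m2a	1	0	0	1	1	0
O1_m2b	1	0	0	1	1	0
O1_m2c	1	0	0	1	1	0
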