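geneX	geneY	phi	dmax	k	C
O1_m1a	O1_m1b	1	0.583333	1	0.198495
O1_m1a	O1_m1c	1	0.583333	1	0.198495
O1_m1a	O1_m1d	1	0.583333	1	0.198495
O1_m1b	O1_m1c	1	0.583333	1	0.198495
O1_m1b	O1_m1d	1	0.583333	1	0.198495
O1_m1c	O1_m1d	1	0.583333	1	0.198495
O1_m2a	O1_m2b	1	0.583333	1	0.198495
O1_m2a	O1_m2c	1	0.583333	1	0.198495
O1_m2b	O1_m2c	1	0.583333	1	0.198495
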