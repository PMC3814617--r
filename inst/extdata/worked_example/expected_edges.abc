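O1_m1a	O1_m1b	0.198495
O1_m1a	O1_m1c	0.198495
O1_m1a	O1_m1d	0.198495
O1_m1b	O1_m1c	0.198495
O1_m1b	O1_m1d	0.198495
O1_m1c	O1_m1d	0.198495
O1_m2a	O1_m2b	0.198495
O1_m2a	O1_m2c	0.198495
O1_m2b	O1_m2c	0.198495
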