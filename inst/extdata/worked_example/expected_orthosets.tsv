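target_gene	organism	ortholog_gene	s	selected
O1_b1	O2	O2_b1	85	1
O1_b1	O3	O3_b1	85	1
O1_b1	O4	O4_b1	85	1
O1_b1	O5	O5_b1	85	1
O1_b1	O6	O6_b1	85	1
O1_b2	O2	O2_b2	80	1
O1_b3	O3	O3_b3	78	1
O1_b3	O4	O4_b3	78	1
O1_b5	O2	O2_b5	75	1
O1_b5	O3	O3_b5	75	1
O1_b5	O4	O4_b5	75	1
O1_b5	O5	O5_b5	75	1
O1_m1a	O2	O2_m1a	92	1
O1_m1a	O3	O3_m1a	92	1
O1_m1a	O6	O6_m1a	92	1
O1_m1b	O2	O2_m1b	92	1
O1_m1b	O3	O3_m1b	92	1
O1_m1b	O6	O6_m1b	92	1
O1_m1c	O2	O2_m1c	92	1
O1_m1c	O3	O3_m1c	92	1
O1_m1c	O6	O6_m1c	92	1
O1_m1d	O2	O2_m1d	92	1
O1_m1d	O3	O3_m1d	92	1
O1_m1d	O6	O6_m1d	92	1
O1_m2a	O4	O4_m2a	88	1
O1_m2a	O5	O5_m2a	88	1
O1_m2b	O4	O4_m2b	88	1
O1_m2b	O5	O5_m2b	88	1
O1_m2c	O4	O4_m2c	88	1
O1_m2c	O5	O5_m2c	88	1
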