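O1_m1a	O2_m1a	92	310
O1_m1a	O3_m1a	92	310
O1_m1a	O6_m1a	92	310
O2_m1a	O3_m1a	92	310
O2_m1a	O6_m1a	92	310
O3_m1a	O6_m1a	92	310
O2_m1a	O1_m1a	92	310
O3_m1a	O1_m1a	92	310
O6_m1a	O1_m1a	92	310
O3_m1a	O2_m1a	92	310
O6_m1a	O2_m1a	92	310
O6_m1a	O3_m1a	92	310
O1_m1b	O2_m1b	92	275
O1_m1b	O3_m1b	92	275
O1_m1b	O6_m1b	92	275
O2_m1b	O3_m1b	92	275
O2_m1b	O6_m1b	92	275
O3_m1b	O6_m1b	92	275
O2_m1b	O1_m1b	92	275
O3_m1b	O1_m1b	92	275
O6_m1b	O1_m1b	92	275
O3_m1b	O2_m1b	92	275
O6_m1b	O2_m1b	92	275
O6_m1b	O3_m1b	92	275
O1_m1c	O2_m1c	92	420
O1_m1c	O3_m1c	92	420
O1_m1c	O6_m1c	92	420
O2_m1c	O3_m1c	92	420
O2_m1c	O6_m1c	92	420
O3_m1c	O6_m1c	92	420
O2_m1c	O1_m1c	92	420
O3_m1c	O1_m1c	92	420
O6_m1c	O1_m1c	92	420
O3_m1c	O2_m1c	92	420
O6_m1c	O2_m1c	92	420
O6_m1c	O3_m1c	92	420
O1_m1d	O2_m1d	92	180
O1_m1d	O3_m1d	92	180
O1_m1d	O6_m1d	92	180
O2_m1d	O3_m1d	92	180
O2_m1d	O6_m1d	92	180
O3_m1d	O6_m1d	92	180
O2_m1d	O1_m1d	92	180
O3_m1d	O1_m1d	92	180
O6_m1d	O1_m1d	92	180
O3_m1d	O2_m1d	92	180
O6_m1d	O2_m1d	92	180
O6_m1d	O3_m1d	92	180
O1_m2a	O4_m2a	88	350
O1_m2a	O5_m2a	88	350
O4_m2a	O5_m2a	88	350
O4_m2a	O1_m2a	88	350
O5_m2a	O1_m2a	88	350
O5_m2a	O4_m2a	88	350
O1_m2b	O4_m2b	88	240
O1_m2b	O5_m2b	88	240
O4_m2b	O5_m2b	88	240
O4_m2b	O1_m2b	88	240
O5_m2b	O1_m2b	88	240
O5_m2b	O4_m2b	88	240
O1_m2c	O4_m2c	88	300
O1_m2c	O5_m2c	88	300
O4_m2c	O5_m2c	88	300
O4_m2c	O1_m2c	88	300
O5_m2c	O1_m2c	88	300
O5_m2c	O4_m2c	88	300
O1_b1	O2_b1	85	500
O1_b1	O3_b1	85	500
O1_b1	O4_b1	85	500
O1_b1	O5_b1	85	500
O1_b1	O6_b1	85	500
O2_b1	O3_b1	85	500
O2_b1	O4_b1	85	500
O2_b1	O5_b1	85	500
O2_b1	O6_b1	85	500
O3_b1	O4_b1	85	500
O3_b1	O5_b1	85	500
O3_b1	O6_b1	85	500
O4_b1	O5_b1	85	500
O4_b1	O6_b1	85	500
O5_b1	O6_b1	85	500
O2_b1	O1_b1	85	500
O3_b1	O1_b1	85	500
O4_b1	O1_b1	85	500
O5_b1	O1_b1	85	500
O6_b1	O1_b1	85	500
O3_b1	O2_b1	85	500
O4_b1	O2_b1	85	500
O5_b1	O2_b1	85	500
O6_b1	O2_b1	85	500
O4_b1	O3_b1	85	500
O5_b1	O3_b1	85	500
O6_b1	O3_b1	85	500
O5_b1	O4_b1	85	500
O6_b1	O4_b1	85	500
O6_b1	O5_b1	85	500
O1_b2	O2_b2	80	220
O2_b2	O1_b2	80	220
O1_b3	O3_b3	78	260
O1_b3	O4_b3	78	260
O3_b3	O4_b3	78	260
O3_b3	O1_b3	78	260
O4_b3	O1_b3	78	260
O4_b3	O3_b3	78	260
O1_b5	O2_b5	75	400
O1_b5	O3_b5	75	400
O1_b5	O4_b5	75	400
O1_b5	O5_b5	75	400
O2_b5	O3_b5	75	400
O2_b5	O4_b5	75	400
O2_b5	O5_b5	75	400
O3_b5	O4_b5	75	400
O3_b5	O5_b5	75	400
O4_b5	O5_b5	75	400
O2_b5	O1_b5	75	400
O3_b5	O1_b5	75	400
O4_b5	O1_b5	75	400
O5_b5	O1_b5	75	400
O3_b5	O2_b5	75	400
O4_b5	O2_b5	75	400
O5_b5	O2_b5	75	400
O4_b5	O3_b5	75	400
O5_b5	O3_b5	75	400
O5_b5	O4_b5	75	400
O2_m1a	O3_b5	30	100
O3_b5	O2_m1a	28	90
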