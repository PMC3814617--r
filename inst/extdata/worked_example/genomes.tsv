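organism	gene	replicon	rank	strand	length
O1	O1_m1a	c1	0	+	310
O1	O1_m1b	c1	1	-	275
O1	O1_m1c	c1	2	+	420
O1	O1_m1d	c1	3	-	180
O1	O1_b1	c1	4	+	500
O1	O1_b2	c1	5	-	220
O1	O1_b3	c1	6	+	260
O1	O1_m2a	p1	0	+	350
O1	O1_m2b	p1	1	-	240
O1	O1_m2c	p1	2	+	300
O1	O1_b4	p1	3	-	330
O1	O1_b5	p1	4	+	400
O2	O2_m1a	c1	0	+	310
O2	O2_m1b	c1	1	-	275
O2	O2_m1c	c1	2	+	420
O2	O2_m1d	c1	3	-	180
O2	O2_b1	c1	4	+	500
O2	O2_b2	c1	5	-	220
O2	O2_b5	c1	6	+	400
O3	O3_m1a	c1	0	+	310
O3	O3_m1b	c1	1	-	275
O3	O3_m1c	c1	2	+	420
O3	O3_m1d	c1	3	-	180
O3	O3_b1	c1	4	+	500
O3	O3_b3	c1	5	-	260
O3	O3_b5	c1	6	+	400
O4	O4_m2a	c1	0	+	350
O4	O4_m2b	c1	1	-	240
O4	O4_m2c	c1	2	+	300
O4	O4_b1	c1	3	-	500
O4	O4_b3	c1	4	+	260
O4	O4_b5	c1	5	-	400
O5	O5_m2a	c1	0	+	350
O5	O5_m2b	c1	1	-	240
O5	O5_m2c	c1	2	+	300
O5	O5_b1	c1	3	-	500
O5	O5_b5	c1	4	+	400
O6	O6_m1a	c1	0	+	310
O6	O6_m1b	c1	1	-	275
O6	O6_m1c	c1	2	+	420
O6	O6_m1d	c1	3	-	180
O6	O6_b1	c1	4	+	500
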