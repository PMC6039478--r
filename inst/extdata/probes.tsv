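probe	atom	element	x	y	z	charge	sigma	epsilon	center
water	O	O	0.0	0.0	0.0	-0.834	3.15061	0.1521	1
water	H1	H	0.7570891	0.0	0.5857580	0.417	0.0	0.0	0
water	H2	H	-0.7570891	0.0	0.5857580	0.417	0.0	0.0	0
methane	C	C	0.0	0.0	0.0	0.0	3.730	0.294	1
acetate	C1	C	0.0	0.0	0.0	0.70	3.750	0.105	1
acetate	O1	O	1.113758	0.0	0.567488	-0.80	2.960	0.210	0
acetate	O2	O	-1.113758	0.0	0.567488	-0.80	2.960	0.210	0
acetate	C2	C	0.0	0.0	-1.520	-0.28	3.500	0.066	0
acetate	H1	H	1.027870	0.0	-1.884060	0.06	2.500	0.030	0
acetate	H2	H	-0.513935	0.890161	-1.884060	0.06	2.500	0.030	0
acetate	H3	H	-0.513935	-0.890161	-1.884060	0.06	2.500	0.030	0
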