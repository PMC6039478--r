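resid	atom	charge	sigma	epsilon
# TIP3P water (trajectory readers use these names)
HOH	O	-0.834	3.15061	0.1521
HOH	H1	0.417	0.0	0.0
HOH	H2	0.417	0.0	0.0
# minimal amino-acid set (AMBER-like values, heavy atoms + polar H)
GLY	N	-0.4157	3.2500	0.1700
GLY	H	0.2719	1.0691	0.0157
GLY	CA	-0.0252	3.3997	0.1094
GLY	C	0.5973	3.3997	0.0860
GLY	O	-0.5679	2.9599	0.2100
ALA	N	-0.4157	3.2500	0.1700
ALA	H	0.2719	1.0691	0.0157
ALA	CA	0.0337	3.3997	0.1094
ALA	CB	-0.1825	3.3997	0.1094
ALA	C	0.5973	3.3997	0.0860
ALA	O	-0.5679	2.9599	0.2100
SER	N	-0.4157	3.2500	0.1700
SER	H	0.2719	1.0691	0.0157
SER	CA	-0.0249	3.3997	0.1094
SER	CB	0.2117	3.3997	0.1094
SER	OG	-0.6546	3.0665	0.2104
SER	HG	0.4275	0.0	0.0
SER	C	0.5973	3.3997	0.0860
SER	O	-0.5679	2.9599	0.2100
ASP	N	-0.5163	3.2500	0.1700
ASP	H	0.2936	1.0691	0.0157
ASP	CA	0.0381	3.3997	0.1094
ASP	CB	-0.0303	3.3997	0.1094
ASP	CG	0.7994	3.3997	0.0860
ASP	OD1	-0.8014	2.9599	0.2100
ASP	OD2	-0.8014	2.9599	0.2100
ASP	C	0.5366	3.3997	0.0860
ASP	O	-0.5819	2.9599	0.2100
PHE	N	-0.4157	3.2500	0.1700
PHE	H	0.2719	1.0691	0.0157
PHE	CA	-0.0024	3.3997	0.1094
PHE	CB	-0.0343	3.3997	0.1094
PHE	CG	0.0118	3.3997	0.0860
PHE	CD1	-0.1256	3.3997	0.0860
PHE	CD2	-0.1256	3.3997	0.0860
PHE	CE1	-0.1704	3.3997	0.0860
PHE	CE2	-0.1704	3.3997	0.0860
PHE	CZ	-0.1072	3.3997	0.0860
PHE	C	0.5973	3.3997	0.0860
PHE	O	-0.5679	2.9599	0.2100
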