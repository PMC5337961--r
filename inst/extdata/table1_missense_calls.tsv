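snp	gene	aa_change	SIFT	PolyPhen2	PROVEAN	FATHMM
rs7578597	THADA	T1187A	Tolerated	benign	Tolerated	Tolerated
rs2228603	NCAN	P92S	Tolerated	probably damaging	Tolerated	Tolerated
rs58542926	TM6SF2	E167K	Tolerated	probably damaging	Tolerated	Tolerated
rs2641348	ADA30	L359P	Tolerated	benign	Tolerated	Tolerated
rs11073964	VP33B	G514S	Tolerated	benign	Tolerated	Tolerated
rs56200889	ARAP1	Q1047E	Tolerated	benign	Tolerated	Tolerated
rs17240268	AMPN	A311V	Tolerated	possibly damaging	Tolerated	Tolerated
rs13266634	ZNT8	R276W	Tolerated	NA	NA	Damaging
rs1801212	WFS1	V333I	Tolerated	benign	Tolerated	Tolerated
rs1801214	WFS1	N500K	Tolerated	NA	Tolerated	Tolerated
rs734312	WFS1	R611H	Tolerated	benign	Tolerated	Tolerated
rs5219	IRK11	K23E	Tolerated	benign	NA	Tolerated
rs757081	NUCB2	Q338E	Tolerated	benign	Tolerated	Tolerated
rs757110	ABCC8	A1369S	Tolerated	benign	Tolerated	Tolerated
rs2276904	UVSSA	R391H	Tolerated	benign	Tolerated	Tolerated
rs1260326	GCKR	L446P	Tolerated	possibly damaging	Tolerated	Tolerated
rs1051334	TSPAN8	S213A	Damaging	benign	Tolerated	Tolerated
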