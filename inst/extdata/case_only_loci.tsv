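position	gene	BD	MDD	SZ	total	ref	alt	aa_change	prediction	haplogroups	catalog_n	self_deposit
3509	ND1	0	1	0	1	T	C	Ile68Thr	benign	H61	3	TRUE
3796	ND1	0	1	1	2	A	G	Thr164Ala	benign	H1b1,H1b1	157	FALSE
3992	ND1	0	0	2	2	C	T	Thr229Met	benign	H4a1a1a,H2a2a1	212	FALSE
4024	ND1	0	0	2	2	A	G	Thr240Ala	benign	H4a1a1a,H2a2a1	166	FALSE
4025	ND1	0	0	1	1	C	T	Thr240Met	benign	H3h	254	FALSE
4561	ND2	0	1	0	1	T	C	Val31Ala	benign	K2a10	221	FALSE
4732	ND2	0	0	1	1	A	G	Asn88Ser	benign	U5b2a1a1b	198	FALSE
4824	ND2	1	0	1	2	A	G	Thr119Ala	possibly damaging	A2d,A2p	746	FALSE
4924	ND2	0	1	0	1	G	C	Ser152Thr	benign	U5a1d2b	7	TRUE
5073	ND2	0	0	1	1	A	G	Ile202Val	benign	K1b2b	1	FALSE
5277	ND2	0	0	1	1	T	C	Phe270Leu	benign	A2p	75	FALSE
5913	COX1	0	0	1	1	G	A	Asp4Asn	benign	K1b2b	191	FALSE
6366	COX1	1	0	0	1	G	A	Val155Ile	benign	A2d	98	FALSE
6480	COX1	0	1	0	1	G	A	Val193Ile	benign	I2d	70	FALSE
8108	COX2	1	0	0	1	A	G	Ile175Val	benign	A2d	45	FALSE
8463	ATP8	1	0	0	1	A	G	Tyr33Cys	probably damaging	X2c1b	8	TRUE
8519	ATP8	0	1	0	1	G	A	Glu52Lys	possibly damaging	I4a	63	FALSE
8794	ATP6	1	0	1	2	C	T	His90Tyr	benign	A2d,A2p	726	FALSE
8843	ATP6	1	0	0	1	T	C	Ile106Thr	possibly damaging	T2b4	119	FALSE
9055	ATP6	0	2	1	3	G	A	Ala177Thr	possibly damaging	K2a10,K1b2b,K1a3a	1401	FALSE
9160	ATP6	1	0	0	1	T	C	Tyr212His	probably damaging	A2d	1	FALSE
9210	COX3	0	0	1	1	A	G	Thr2Ala	benign	H1ag	33	FALSE
11016	ND4	1	0	0	1	G	A	Ser86Asn	benign	H48	184	FALSE
11204	ND4	1	0	0	1	T	C	Phe149Leu	benign	H1	100	FALSE
12346	ND5	0	0	1	1	C	T	His4Tyr	unknown	U2e1c	168	FALSE
12397	ND5	1	0	0	1	A	G	Thr21Ala	unknown	X2a2	134	FALSE
12811	ND5	0	0	1	1	T	C	Tyr159His	benign	H3h	214	FALSE
13117	ND5	0	1	0	1	A	G	Ile261Val	possibly damaging	K1a3a	47	FALSE
13637	ND5	0	0	1	1	A	G	Gln434Arg	benign	U5b2a1a1b	243	FALSE
13708	ND5	1	0	1	2	G	A	Ala458Thr	benign	J1c2o,U5b2a1a1b	1912	FALSE
14110	ND5	0	1	0	1	T	C	Phe592Leu	benign	H1	247	FALSE
14280	ND6	0	0	1	1	A	C	Ser132Ala	benign	U2e1c	2	FALSE
14502	ND6	1	0	0	1	T	C	Ile58Val	benign	X2a2	111	FALSE
14582	ND6	0	0	2	2	A	G	Val31Ala	benign	H4a1a1a,H2a2a1	164	FALSE
14798	CYTB	1	2	1	4	T	C	Phe18Leu	benign	J1c2o,K2a10,K1b2b,K1a3a	2114	FALSE
14982	CYTB	0	1	0	1	T	C	Ile79Thr	possibly damaging	V16	2	FALSE
15431	CYTB	1	0	0	1	G	A	Ala229Thr	benign	I3b	326	FALSE
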