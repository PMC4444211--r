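gene	position	ref	alt	coverage	aa_change	prediction	age	gender	diagnosis	haplogroup	status
ATP6	8945	T	C	2820	Met140Thr	damaging	55	M	C	H1	Rare
ATP6	8642	A	C	2572	Asn39Thr	damaging	54	M	C	I1	Novel
ATP6	9160	T	C	28247	Tyr212His	damaging	50	M	BD	A2d	Novel
CYTB	14982	T	C	12465	Ile79Thr	moderate	41	F	MDD	V16	Rare
ND6	14280	A	C	1113	Ser132Ala	benign	36	M	SZ	U2e1c	Novel
ND2	5073	A	G	20128	Ile202Val	benign	40	F	SZ	K1b2b	Novel
D-loop	16178	T	G	22475			35	M	SZ	A2p	Novel
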