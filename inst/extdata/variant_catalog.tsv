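position	alt	count	catalog_size	self_deposit
3509	C	3	26850	TRUE
3796	G	157	26850	FALSE
3992	T	212	26850	FALSE
4024	G	166	26850	FALSE
4025	T	254	26850	FALSE
4561	C	221	26850	FALSE
4732	G	198	26850	FALSE
4824	G	746	26850	FALSE
4924	C	7	26850	TRUE
5073	G	1	26850	FALSE
5277	C	75	26850	FALSE
5913	A	191	26850	FALSE
6366	A	98	26850	FALSE
6480	A	70	26850	FALSE
8108	G	45	26850	FALSE
8463	G	8	26850	TRUE
8519	A	63	26850	FALSE
8794	T	726	26850	FALSE
8843	C	119	26850	FALSE
9055	A	1401	26850	FALSE
9160	C	1	26850	FALSE
9210	G	33	26850	FALSE
11016	A	184	26850	FALSE
11204	C	100	26850	FALSE
12346	T	168	26850	FALSE
12397	G	134	26850	FALSE
12811	C	214	26850	FALSE
13117	G	47	26850	FALSE
13637	G	243	26850	FALSE
13708	A	1912	26850	FALSE
14110	C	247	26850	FALSE
14280	C	2	26850	FALSE
14502	C	111	26850	FALSE
14582	G	164	26850	FALSE
14798	C	2114	26850	FALSE
14982	C	2	26850	FALSE
15431	A	326	26850	FALSE
8945	C	1	26850	FALSE
8642	C	0	26850	FALSE
16178	G	0	26850	FALSE
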