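position	ref	alt	reason
302	A	C	motif_AC
3492	A	C	motif_AC
6419	A	C	motif_AC
10306	A	C	motif_AC
3488	T	A	blacklist
6415	T	A	blacklist
9801	G	T	blacklist
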