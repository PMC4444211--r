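name	start	end	strand	kind	incomplete_stop
tRNA-Phe	577	647	H	tRNA	FALSE
RNR1	648	1601	H	rRNA	FALSE
tRNA-Val	1602	1670	H	tRNA	FALSE
RNR2	1671	3229	H	rRNA	FALSE
tRNA-Leu1	3230	3304	H	tRNA	FALSE
ND1	3307	4262	H	protein	TRUE
tRNA-Ile	4263	4331	H	tRNA	FALSE
tRNA-Gln	4329	4400	L	tRNA	FALSE
tRNA-Met	4402	4469	H	tRNA	FALSE
ND2	4470	5511	H	protein	TRUE
tRNA-Trp	5512	5579	H	tRNA	FALSE
tRNA-Ala	5587	5655	L	tRNA	FALSE
tRNA-Asn	5657	5729	L	tRNA	FALSE
tRNA-Cys	5761	5826	L	tRNA	FALSE
tRNA-Tyr	5826	5891	L	tRNA	FALSE
COX1	5904	7445	H	protein	FALSE
tRNA-Ser1	7446	7514	L	tRNA	FALSE
tRNA-Asp	7518	7585	H	tRNA	FALSE
COX2	7586	8269	H	protein	FALSE
tRNA-Lys	8295	8364	H	tRNA	FALSE
ATP8	8366	8572	H	protein	FALSE
ATP6	8527	9207	H	protein	FALSE
COX3	9207	9990	H	protein	TRUE
tRNA-Gly	9991	10058	H	tRNA	FALSE
ND3	10059	10404	H	protein	TRUE
tRNA-Arg	10405	10469	H	tRNA	FALSE
ND4L	10470	10766	H	protein	FALSE
ND4	10760	12137	H	protein	TRUE
tRNA-His	12138	12206	H	tRNA	FALSE
tRNA-Ser2	12207	12265	H	tRNA	FALSE
tRNA-Leu2	12266	12336	H	tRNA	FALSE
ND5	12337	14148	H	protein	FALSE
ND6	14149	14673	L	protein	FALSE
tRNA-Glu	14674	14742	L	tRNA	FALSE
CYTB	14747	15887	H	protein	TRUE
tRNA-Thr	15888	15953	H	tRNA	FALSE
tRNA-Pro	15956	16023	L	tRNA	FALSE
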