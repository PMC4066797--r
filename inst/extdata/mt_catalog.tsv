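position	trna	symbol	gene_confirmed	gene_predicted
6	Asp	m2G		THUMPD3 or THUMPD2
9	Ala	m1A	TRMT10C and SDR5C1	
9	Asp	m1A	TRMT10C and SDR5C1	
9	Glu	m1A	TRMT10C and SDR5C1	
9	Phe	m1A	TRMT10C and SDR5C1	
9	Gly	m1A	TRMT10C and SDR5C1	
9	His	m1A	TRMT10C and SDR5C1	
9	Lys	m1A	TRMT10C and SDR5C1	
9	Leu(CUN)	m1A	TRMT10C and SDR5C1	
9	Asn	m1A	TRMT10C and SDR5C1	
9	Pro	m1A	TRMT10C and SDR5C1	
9	Arg	m1A	TRMT10C and SDR5C1	
9	Thr	m1A	TRMT10C and SDR5C1	
9	Val	m1A	TRMT10C and SDR5C1	
9	Trp	m1A	TRMT10C and SDR5C1	
9	Cys	m1G	TRMT10C and SDR5C1	
9	Ile	m1G	TRMT10C and SDR5C1	
9	Leu(UUR)	m1G	TRMT10C and SDR5C1	
9	Gln	m1G	TRMT10C and SDR5C1	
9	Tyr	m1G	TRMT10C and SDR5C1	
10	Ala	m2G		TRMT11 and TRMT112
10	Phe	m2G		TRMT11 and TRMT112
10	Gly	m2G		TRMT11 and TRMT112
10	His	m2G		TRMT11 and TRMT112
10	Lys	m2G		TRMT11 and TRMT112
10	Leu(UUR)	m2G		TRMT11 and TRMT112
10	Leu(CUN)	m2G		TRMT11 and TRMT112
10	Asn	m2G		TRMT11 and TRMT112
10	Pro	m2G		TRMT11 and TRMT112
10	Val	m2G		TRMT11 and TRMT112
10	Trp	m2G		TRMT11 and TRMT112
10	Tyr	m2G		TRMT11 and TRMT112
20	Leu(UUR)	D		DUS2
20	Leu(CUN)	D		DUS2
20	Ser(UCN)	D		DUS2
26	Ala	m2G		TRMT1
26	Glu	m2G		TRMT1
26	Leu(UUR)	m2G		TRMT1
26	Ile	m22G		TRMT1
27a	Ser(UCN)	Y		PUS1
27	Cys	Y	PUS1	
27	Asp	Y	PUS1	
27	His	Y	PUS1	
27	Ile	Y	PUS1	
27	Leu(UUR)	Y	PUS1	
27	Leu(CUN)	Y	PUS1	
27	Asn	Y	PUS1	
27	Pro	Y	PUS1	
27	Val	Y	PUS1	
27	Met	Y	PUS1	
28	Ala	Y	PUS1	
28	Cys	Y	PUS1	
28	Glu	Y	PUS1	
28	Lys	Y	PUS1	
28	Leu(CUN)	Y	PUS1	
28	Asn	Y	PUS1	
28	Ser(UCN)	Y	PUS1	
28	Tyr	Y	PUS1	
29	Ser(UCN)	Y		PUS1
31	Asp	Y		RPUSD1, RPUSD2, RPUSD3 or RPUSD4
31	Leu(CUN)	Y		RPUSD1, RPUSD2, RPUSD3 or RPUSD4
32	Cys	Y		RPUSD1, RPUSD2, RPUSD3 or RPUSD4
32	Val	Y		RPUSD1, RPUSD2, RPUSD3 or RPUSD4
32	Ser(UCN)	m3C		METTL2B
32	Thr	m3C		METTL2B
34	Leu(UUR)	tm5U		GTPBP3 and MTO1
34	Trp	tm5U		GTPBP3 and MTO1
34	Glu	tm5U		GTPBP3 and MTO1
34	Lys	tm5U		GTPBP3 and MTO1
34	Gln	tm5U		GTPBP3 and MTO1
34	Glu	tm5s2U	MTU1 and NFS1	
34	Lys	tm5s2U	MTU1 and NFS1	
34	Gln	tm5s2U	MTU1 and NFS1	
34	Met	f5C		unidentified
34	Asp	Q	QTRT1 and QTRTD1	
34	His	Q	QTRT1 and QTRTD1	
34	Asn	Q	QTRT1 and QTRTD1	
34	Tyr	Q	QTRT1 and QTRTD1	
37	Ile	t6A		YRDC and OSGEPL1
37	Lys	t6A		YRDC and OSGEPL1
37	Asn	t6A		YRDC and OSGEPL1
37	Ser(AGY)	t6A		YRDC and OSGEPL1
37	Thr	t6A		YRDC and OSGEPL1
37	Cys	i6A	TRIT1	
37	Phe	i6A	TRIT1	
37	Ser(UCN)	i6A	TRIT1	
37	Trp	i6A	TRIT1	
37	Tyr	i6A	TRIT1	
37	Phe	ms2i6A	CDK5RAP1	
37	Ser(UCN)	ms2i6A	CDK5RAP1	
37	Trp	ms2i6A	CDK5RAP1	
37	Tyr	ms2i6A	CDK5RAP1	
37	Leu(CUN)	m1G	TRMT5	
37	Pro	m1G	TRMT5	
37	Gln	m1G	TRMT5	
39	Ala	Y		PUS3
39	Cys	Y		PUS3
39	Phe	Y		PUS3
39	Gly	Y		PUS3
39	His	Y		PUS3
39	Leu(UUR)	Y		PUS3
39	Gln	Y		PUS3
39	Arg	Y		PUS3
39	Tyr	Y		PUS3
40	Glu	Y		PUS3
40	Gln	Y		PUS3
48	Leu(UUR)	m5C	NSUN2	
48	Asn	m5C	NSUN2	
48	Trp	m5C	NSUN2	
49	Glu	m5C	NSUN2	
49	Ser(AGY)	m5C	NSUN2	
50	Met	Y		unidentified
55	Glu	Y		TRUB2
55	Gln	Y		TRUB2
55	Ser(UCN)	Y		TRUB2
55	Tyr	Y		TRUB2
57	Ala	Y		unidentified
58	Cys	m1A	TRMT61B	
58	Glu	m1A	TRMT61B	
58	Ile	m1A	TRMT61B	
58	Lys	m1A	TRMT61B	
58	Leu(UUR)	m1A	TRMT61B	
58	Ser(UCN)	m1A	TRMT61B	
67	Thr	Y		PUS1
72	Thr	m5C		unidentified
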