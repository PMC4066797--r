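trna	a34	a35	a36
Phe	G	A	A
Leu(UUR)	tm5U	A	A
Leu(CUN)	U	A	G
Ile	G	A	U
Met	f5C	A	U
Val	U	A	C
Ser(UCN)	U	G	A
Ser(AGY)	G	C	U
Pro	U	G	G
Thr	U	G	U
Ala	U	G	C
Tyr	Q	U	A
His	Q	U	G
Gln	tm5s2U	U	G
Asn	Q	U	U
Lys	tm5s2U	U	U
Asp	Q	U	C
Glu	tm5s2U	U	C
Cys	G	C	A
Trp	tm5U	C	A
Arg	U	C	G
Gly	U	C	C
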