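record_id	index	label	symbol	alleles	partial
Ala	9	9	m1A		FALSE
Ala	10	10	m2G		TRUE
Ala	26	26	m2G		FALSE
Ala	28	28	Y		FALSE
Ala	39	39	Y		FALSE
Ala	57	57	Y		FALSE
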