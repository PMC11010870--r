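source	target	sign	is_directed	confidence
MAPK1	STAT3	1	1	A
GSK3B	MYC	-1	1	A
FOXO3	AKT1	-1	1	B
ORPHAN1	ORPHAN2	1	1	A
NOSIGN1	TP53	NA	1	A
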