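source	target	sign	is_directed	confidence
TP53	MDM2	1	1	A
MYC	TP53	-1	1	A
AKT1	GSK3B	-1	1	A
EGFR	KRAS	1	1	A
KRAS	MAPK1	1	1	A
STAT3	MYC	1	1	A
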