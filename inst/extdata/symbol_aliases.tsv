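alias	symbol
TNFA	TNF
TNFALPHA	TNF
IL1BETA	IL1B
IFNGAMMA	IFNG
P53	TP53
COX2	PTGS2
CJUN	JUN
NFKB1A	NFKBIA
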