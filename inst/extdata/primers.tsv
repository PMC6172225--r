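name	marker	direction	sequence
mlCOIintR	COI	reverse	GGRGGRTASACSGTTCASCCSGTSCC
mlCOIintK	COI	reverse	GGRGGRTAWACWGTTCAWCCWGTWCC
nsCOIFo	COI	forward	THATRATNGGNGGNTTYGGNAAHTG
18S#4	18S	forward	AGGTCWGTRATGCCCTYMG
18S#5_RC	18S	reverse	TGYACAAAGGBCAGGGACC
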