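marker	direction	tag
COI	forward	actgac
COI	forward	gtagca
COI	forward	gacagt
COI	forward	tgtacg
COI	forward	catctg
COI	reverse	gacgta
COI	reverse	tctgag
COI	reverse	gctagt
COI	reverse	agcact
COI	reverse	agagac
18S	forward	gtca
18S	forward	catg
18S	forward	acgt
18S	forward	tagc
18S	forward	agac
18S	reverse	actc
18S	reverse	gaga
18S	reverse	ctct
18S	reverse	gcat
18S	reverse	tgag
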