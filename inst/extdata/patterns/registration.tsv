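indicator	code	polarity	zone	needs_context	ignore_case	pattern	note
registration	a	positive	all	0	1	\bregister(ed)?\s+(prospectively\s+|retrospectively\s+)?(on|at|in|with)\s+clinicaltrials\.gov\b	ClinicalTrials.gov registration
registration	a	positive	all	0	1	\bclinicaltrials\.gov\b[^.!?]{0,60}\bNCT\d{8}\b	ClinicalTrials.gov with identifier
registration	b	positive	all	0	1	\bregister(ed)?\s+(on|at|in|with)\s+PROSPERO\b	PROSPERO registration
registration	b	positive	all	0	1	\bPROSPERO\b[^.!?]{0,40}\bCRD\d{8,11}\b	PROSPERO with identifier
registration	c	positive	all	0	1	\b(protocol|study|trial)\s+(was|were|is|has\s+been)\s+(prospectively\s+|retrospectively\s+|publicly\s+)?registered\b	registration regardless of registry
registration	c	positive	all	0	1	\bregistration\s+of\s+(this|the|our)\s+(trial|study|protocol)\s+was\s+(completed|performed|undertaken|carried\s+out)\b	passive reordering
registration	c	positive	all	0	1	\bwe\s+(prospectively\s+|retrospectively\s+)?registered\s+(this|the|our)\s+(trial|study|protocol)\b	active form
registration	c	positive	all	0	1	\bregister(ed)?\s+(on|at|in|with)\s+the\s+[A-Za-z ]{0,40}(clinical\s+trials?\s+regist(er|ry)|trials?\s+regist(er|ry)|register)\b	named register regardless of registry
registration	d	positive	all	0	1	\b(protocol|study|trial|research)\s+(protocol\s+)?(is|are|was|were)\s+(publicly\s+|openly\s+)?available\s+(on|at|in)\s+[^!?]{0,60}\bregist(ry|er)\b	availability on a register
registration	e	positive	heading	0	1	^((trial|study|protocol|clinical\s+trial)\s+)?registration(\s+(number|no\.?))?\s*[:.]?\s*$	registration section titles
registration	e	positive	all	0	1	^\s*(trial|study|protocol)\s+registration\s*(number|no\.?)?\s*:	registration title leading a paragraph
registration	e	positive	all	0	1	\btrial\s+registration\s*:?\s*\(?(NCT\d{8}|ISRCTN\d{6,8}|CRD\d{8,11}|ChiCTR[-A-Za-z0-9]{4,}|ACTRN\d{14}|UMIN\d{9})	registration title with identifier
registration	f	positive	all	0	1	\b(study\s+|trial\s+)?protocol\s+(was|has\s+been)\s+(previously\s+|already\s+)?published\b	previously published protocol
registration	g	positive	all	0	1	\b(funded|supported)\s+by\b[^\n]{0,200}?\b(NCT\d{8}|CRD\d{8,11}|ISRCTN\d{6,8}|ChiCTR[-A-Za-z0-9]{4,}|ACTRN\d{14}|UMIN\d{9})\b	registration inside a funding disclosure
registration	.	negation	all	0	1	\b(hospital|cancer|national|regional|state|birth|death|patient|disease|tumou?r|surgical|trauma|transplant|population[- ]based|institutional|prospective)\s+registr(y|ies)\b	non-registry registry mentions
registration	.	negation	all	0	1	\benrol(l)?ed\s+[^.!?]{0,80}\bregistr(y|ies)\b	enrolment in a registry
registration	.	negation	all	0	1	\bregistr(y|ies)\s+(data|records?|database)\b	registry as a data source
registration	.	negation	all	0	1	\bapprov\w+\s+by\s+[^.!?]{0,80}registration\s+(no\.?|number)\s*:?\s*\d+\s*\)?	approval-only registration numbers
registration	.	negation	all	0	1	\bethics\s+[^.!?]{0,40}registration\s+(no\.?|number)\b	ethics approval numbers
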