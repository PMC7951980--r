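indicator	code	polarity	zone	needs_context	ignore_case	pattern	note
coi	a	positive	all	0	1	\b(conflicts?\s+of\s+interest|competing\s+(financial\s+)?interests?|declarations?\s+of\s+(competing\s+)?interest)\b	disclosure-associated phrases
coi	b	positive	heading	0	1	^(conflicts?\s+of\s+interests?|competing\s+interests?|declaration\s+of\s+(competing\s+)?interests?|disclosures?|financial\s+disclosures?|disclosure\s+statement|conflict\s+of\s+interest\s+statement)\s*[:.]?\s*$	section titles
coi	b	positive	all	0	1	^(conflicts?\s+of\s+interests?|competing\s+interests?|disclosure\s+statement)\s*:	section title leading a paragraph
coi	c	positive	all	0	1	\breceiv\w+\s+(commercial\s+benefits?|consult\w*\s+fees?|personal\s+fees|honorari\w+|speaker\s+fees?)\s+from\b	declared-conflict phrases
coi	c	positive	all	0	1	\b(has|have|had|maintains?|reports?|declares?)\s+(a\s+|an\s+)?(financial|commercial)\s+relationships?\s+with\b	declared-conflict phrases
coi	c	positive	all	0	1	\bis\s+a\s+paid\s+(consultant|adviser|advisor)\s+(for|to|of)\b	declared-conflict phrases
coi	c	positive	all	0	1	\bserves?\s+on\s+the\s+(advisory\s+boards?|speakers?\s+bureaus?)\s+(of|for)\b	declared-conflict phrases
coi	d	positive	all	0	1	\bno\s+(potential\s+|known\s+|relevant\s+)?(conflicts?\s+of\s+interest|competing\s+(financial\s+)?interests?)\b	no-conflict declarations
coi	d	positive	all	0	1	\bnothing\s+to\s+disclose\b	no-conflict declarations
coi	d	positive	all	0	1	\bno\s+conflicts?\s+(of\s+interest\s+)?(to\s+declare|to\s+disclose|to\s+report|exists?)\b	no-conflict declarations
coi	e	positive	ack	0	1	\b(fees|speakers?\s+bureaus?|advisory\s+boards?|honorari(a|um)|consultanc(y|ies)|stockholders?|equity\s+holdings?)\b	acknowledgment-localized sensitive words
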