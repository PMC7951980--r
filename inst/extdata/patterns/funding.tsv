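indicator	code	polarity	zone	needs_context	ignore_case	pattern	note
funding	a	positive	all	0	1	\b(this|the\s+present)\s+(study|work|research|project|trial)\s+was\s+(financially\s+|partially\s+|partly\s+|generously\s+|kindly\s+)?(supported|funded|financed|sponsored)\s+by\b	disclosure phrases
funding	a	positive	all	0	1	\bwe\s+acknowledge\s+(the\s+)?financial\s+support\s+(by|from)\b	disclosure phrases
funding	a	positive	all	0	1	\bfinancial\s+support\s+(for\s+(this|the)\s+(study|work|research|article)\s+)?was\s+provided\s+by\b	passive form
funding	a	positive	all	0	1	\b(funded|supported|financed|sponsored)\s+this\s+(study|work|research|project)\b	active reordering
funding	a	positive	all	0	1	\b(study|work|research|project|trial)\s+(was|were|is|has\s+been)\s+(financially\s+|partially\s+|partly\s+)?(supported|funded|financed)\s+by\b	passive reordering
funding	b	positive	heading	0	1	^(funding|funding\s+(information|sources?|statement)|financial\s+support|sources?\s+of\s+(funding|support)|grant\s+support)\s*[:.]?\s*$	section titles
funding	b	positive	all	0	1	^(funding|financial\s+support|grant\s+support)\s*:	section title leading a paragraph
funding	c	positive	all	0	1	\breceived?\s+financial\s+support\s+(by|from)\b	foundation support
funding	c	positive	all	0	1	\bsupport(ed)?\s+by\s+(a\s+grant\s+from\s+)?the\s+[\w .&-]{0,60}(foundation|trust|charity|council|society|ministry|institutes?\s+of\s+health)\b	foundation support
funding	d	positive	all	0	1	\b(the\s+|this\s+)?authors?\s+(has|have)\s+received\s+(no\s+)?(specific\s+)?(financial\s+support|funding|grants?)\b	author-referenced statements
funding	d	positive	all	0	1	\b(the\s+|this\s+)?authors?\s+received\s+(no\s+)?(specific\s+)?(funding|financial\s+support|grants?)\b	author-referenced statements
funding	e	positive	all	0	1	\bwe\s+thank\s+[^.!?]{0,80}\bfor\s+(its\s+|their\s+|the\s+)?(generous\s+)?(financial\s+support|funding)\b	thank-you statements
funding	e	positive	all	0	1	\bgrateful\s+(to\s+)?[^.!?]{0,80}\bfor\s+(funding|financial\s+support)\b	thank-you statements
funding	f	positive	all	0	1	\b(grant|award)\s+(numbers?|nos?\.|#)\s*:?\s*[A-Za-z0-9][\w/.-]*	awards and grants
funding	f	positive	all	0	1	\b(supported|funded)\s+by\s+[^.!?]{0,80}\bgrants?\b	awards and grants
funding	f	positive	all	0	1	\bunder\s+grant\s+(agreement\s+)?(nos?\.|numbers?\s*)?\s*:?\s*[A-Za-z0-9][\w/.-]*	awards and grants
funding	g	positive	all	0	1	\bno\s+(specific\s+|external\s+|dedicated\s+)?funding\s+was\s+(received|obtained|provided|sought)\b	no-funding statements
funding	g	positive	all	0	1	\breceived\s+no\s+(specific\s+|external\s+)?(funding|financial\s+support)\b	no-funding statements
funding	g	positive	all	0	1	\bno\s+financial\s+support\s+was\s+received\b	no-funding statements
funding	g	positive	all	0	1	\bdid\s+not\s+receive\s+any\s+(specific\s+)?(grant|funding|financial\s+support)\b	no-funding statements
funding	g	positive	all	0	1	\b(study|research|work)\s+received\s+no\s+(specific\s+|external\s+)?(grant|funding)\b	no-funding statements
funding	h	positive	ack	0	1	\b(funded\s+by|funding\s+(from|by)|financial\s+support|grant\s+(nos?\.|numbers?)|supported\s+by\s+grants?)\b	acknowledgment-localized funding words
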