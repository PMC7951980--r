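indicator	code	polarity	zone	needs_context	ignore_case	pattern	note
code_sharing	c	positive	all	1	1	\b(code|codes|scripts?|software|pipeline|package|notebooks?)\b[^.!?]{0,60}\b(github|gitlab|bitbucket|sourceforge)\b	online repositories (code first)
code_sharing	c	positive	all	1	1	\b(github|gitlab|bitbucket|sourceforge)\b[^.!?]{0,60}\b(code|codes|scripts?|software|pipeline|package|notebooks?)\b	online repositories (repository first)
code_sharing	d	positive	all	1	0	\b(python|Python|R|perl|Perl|MATLAB|Matlab|matlab|julia|Julia|shell)\s+(script|scripts|code|notebook|notebooks|package)\b	code-availability language
code_sharing	d	positive	all	1	1	\b(source\s+code|analysis\s+(code|scripts?)|custom\s+(code|scripts?)|computer\s+code)\b	code-availability language
code_sharing	d	positive	all	0	1	\b(all\s+)?(analysis\s+)?(code|scripts?)\s+(is|are|was|were|has\s+been|have\s+been)\s+(made\s+)?(openly\s+|publicly\s+|freely\s+)?available\b	code-availability statements
code_sharing	.	context	all	0	1	\b(deposited|deposit|uploaded|download(ed|able)?|accessible|accessed|available|availability|released|submitted|shared|sharing|archived|hosted|obtained\s+from|can\s+be\s+found)\b	positive-context cues
code_sharing	.	negation	all	0	1	\b(up)?on\s+(reasonable\s+)?request\b	request-only availability
code_sharing	.	negation	all	0	1	\bnot\s+(be\s+)?(made\s+)?(publicly\s+|openly\s+)?(deposited|available|shared|released|uploaded)\b	negative statements
code_sharing	.	negation	all	0	1	\bavailable\s+(from|through)\s+the\s+(corresponding\s+|first\s+)?authors?\b	author-held code
code_sharing	.	negation	all	0	1	\bno\s+custom\s+code\b	no custom code statements
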