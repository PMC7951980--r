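indicator	code	polarity	zone	needs_context	ignore_case	pattern	note
data_sharing	a	positive	all	1	1	\b(figshare|dryad|zenodo|mendeley\s+data|dataverse|open\s+science\s+framework|osf\.io)\b	general databases
data_sharing	b	positive	all	1	1	\b(dbSNP|GenBank|ArrayExpress|UniProt|dbGaP|PRIDE|MetaboLights|FlyBase|ImmPort|Gene\s+Expression\s+Omnibus|Sequence\s+Read\s+Archive|Protein\s+Data\s+Bank|European\s+Nucleotide\s+Archive)\b	field-specific databases
data_sharing	b	positive	all	1	0	\b(GEO|SRA|PDB|ENA|EGA|TCGA)\b	field-specific database acronyms (case-sensitive)
data_sharing	b	positive	all	1	1	\baccession\s+(numbers?|codes?|nos?\.)\b	accession language
data_sharing	c	positive	all	1	1	\b(data|datasets?|raw\s+measurements?)\b[^.!?]{0,60}\b(github|gitlab|bitbucket|sourceforge)\b	online repositories (data first)
data_sharing	c	positive	all	1	1	\b(github|gitlab|bitbucket|sourceforge)\b[^.!?]{0,60}\b(data|datasets?)\b	online repositories (repository first)
data_sharing	e	positive	all	1	1	\b(csv|tsv|xlsx|fasta|fastq|sav|rdata)\s+(files?|format)\b	shared file formats
data_sharing	e	positive	all	1	1	\bas\s+(a\s+)?(csv|excel|spreadsheet)\b	shared file formats
data_sharing	f	positive	all	1	1	\bsupplementar\w+\s+(data|datasets?|tables?|files?|information|materials?)\b	supplement-data language
data_sharing	g	positive	all	0	1	\bdata\s+availability\s+statement\b	availability-statement language
data_sharing	g	positive	all	0	1	\b(all|the)\s+(relevant\s+|raw\s+|underlying\s+)?data\s+(generated|analys\w+|used|supporting)?[^.!?]{0,40}\b(are|is|were|have\s+been|has\s+been)\s+(openly\s+|publicly\s+|freely\s+)?(available|deposited|included|accessible)\b	availability-statement language
data_sharing	g	positive	all	0	1	\bdata\s+(are|is|were|have\s+been)\s+(openly|publicly|freely)\s+available\b	availability-statement language
data_sharing	.	context	all	0	1	\b(deposited|deposit|uploaded|download(ed|able)?|accessible|accessed|available|availability|released|submitted|shared|sharing|archived|hosted|obtained\s+from|can\s+be\s+found)\b	positive-context cues
data_sharing	.	negation	all	0	1	\b(up)?on\s+(reasonable\s+)?request\b	request-only availability
data_sharing	.	negation	all	0	1	\bnot\s+(be\s+)?(made\s+)?(publicly\s+|openly\s+)?(deposited|available|shared|released|uploaded)\b	negative statements
data_sharing	.	negation	all	0	1	\bavailable\s+(from|through)\s+the\s+(corresponding\s+|first\s+)?authors?\b	author-held data
data_sharing	.	negation	all	0	1	\bno\s+(new\s+)?data\s+(were|was|are)\s+(generated|created)\b	no data generated
data_sharing	.	negation	all	0	1	\bdata\s+sharing\s+(is\s+)?not\s+applicable\b	not applicable statements
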