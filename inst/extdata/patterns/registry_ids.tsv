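registry	pattern
clinicaltrials_gov	NCT\d{8}
prospero	CRD\d{8,11}
chictr	ChiCTR[-A-Za-z0-9]{4,}
isrctn	ISRCTN\d{6,8}
anzctr	ACTRN\d{14}
umin	UMIN\d{9}
eudract	\d{4}-\d{6}-\d{2}
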