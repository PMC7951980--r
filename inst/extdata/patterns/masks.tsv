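name	applies_to	ignore_case	pattern	note
coi_finance_relationship	funding	1	\b[\w.]+(?:[,; ]+[\w.]+){0,3}\s+(has|have|had|maintains?|reports?|declares?)\s+(a\s+|an\s+)?(financial|commercial)\s+relationships?\s+with\b[^.;!?]*	finance wording inside COI disclosures
coi_fees	funding	1	\b[\w.]+\s+receiv\w+\s+(commercial\s+benefits?|consult\w*\s+fees?|personal\s+fees|honorari\w+|speaker\s+fees?)\s+from\b[^.;!?]*	fee wording inside COI disclosures (extrapolated)
coi_paid_consultant	funding	1	\b[\w.]+\s+is\s+a\s+paid\s+(consultant|adviser|advisor)\s+(for|to|of)\b[^.;!?]*	consultancy wording inside COI disclosures (extrapolated)
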