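kind	ignore_case	pattern
acknowledgments	1	^acknowledge?ments?\s*[:.]?\s*$
coi_statement	1	^(conflicts?\s+of\s+interests?|competing\s+interests?|declaration\s+of\s+(competing\s+)?interests?|disclosures?|financial\s+disclosures?|disclosure\s+statement|conflict\s+of\s+interest\s+statement)\s*[:.]?\s*$
funding_statement	1	^(funding|funding\s+(information|sources?|statement)|financial\s+support|sources?\s+of\s+(funding|support)|grant\s+support)\s*[:.]?\s*$
methods	1	^((materials?\s+and\s+)?methods(\s+and\s+materials?)?|experimental\s+procedures|study\s+design|patients\s+and\s+methods)\s*[:.]?\s*$
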