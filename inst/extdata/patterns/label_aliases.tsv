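group	alias
usa	USA
usa	United States
usa	United States of America
usa	U.S.A.
usa	US
usa	U.S.
uk	UK
uk	United Kingdom
uk	U.K.
uk	Great Britain
china	China
china	People's Republic of China
china	PR China
china	P.R. China
korea	South Korea
korea	Republic of Korea
korea	Korea
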