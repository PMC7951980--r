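flag	xpath
coi_tagged	//fn[@fn-type='conflict']
coi_tagged	//fn[@fn-type='COI-statement']
coi_tagged	//fn[@fn-type='coi-statement']
coi_tagged	//notes[@notes-type='COI-statement']
coi_tagged	//sec[@sec-type='COI-statement']
funding_tagged	//funding-group
funding_tagged	//fn[@fn-type='financial-disclosure']
data_tagged	//sec[@sec-type='data-availability']
data_tagged	//notes[@notes-type='data-availability']
data_tagged	//fn[@fn-type='data-availability']
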