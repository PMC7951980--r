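no.
No.
nos.
Nos.
Dr.
Prof.
Mr.
Mrs.
Ms.
St.
vs.
etc.
al.
e.g.
i.e.
Fig.
Figs.
fig.
Eq.
Ref.
Refs.
ca.
cf.
approx.
Inc.
Ltd.
Co.
Jr.
Sr.
wt.
vol.
pp.
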