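template_id	indicator	category	tier	zone	also_sets	text
coi_a_v1	coi	a	verbatim	back		The authors have read the journal's policy and declare the following conflicts of interest in relation to this work.
coi_b_v1	coi	b	verbatim	coi_section		The statements above describe all relevant relationships of the author group.
coi_c_v1	coi	c	verbatim	back		S.S. maintains a financial relationship with GSK.
coi_d_v1	coi	d	verbatim	back		The authors declare no competing interests.
coi_d_v2	coi	d	verbatim	back		The authors have nothing to disclose.
coi_e_v1	coi	e	verbatim	ack		The lead investigator reported honoraria and membership of the advisory board of Acme Pharma.
coi_a_p1	coi	a	paraphrase	back		Potential conflicts of interest were reviewed and are reported within this statement.
coi_d_p1	coi	d	paraphrase	back		No competing interests are reported by the authors.
fund_a_v1	funding	a	verbatim	back		This study was financially supported by the National Research Council.
fund_b_v1	funding	b	verbatim	funding_section		Institutional resources were also made use of during this project.
fund_c_v1	funding	c	verbatim	back		S.S. received financial support by the NIH.
fund_d_v1	funding	d	verbatim	back		This author has received no financial support for this research.
fund_e_v1	funding	e	verbatim	ack		We thank the NIH for its financial support.
fund_f_v1	funding	f	verbatim	back		This work was supported by Grant no. 12345.
fund_g_v1	funding	g	verbatim	back		No funding was received for this research.
fund_h_v1	funding	h	verbatim	ack		This project was funded by the National Institutes of Health.
fund_a_p1	funding	a	paraphrase	back		Financial support for this work was provided by the Kavli Trust.
fund_f_p1	funding	f	paraphrase	back		The analyses were funded under grant agreement no. 2021-774 from a charitable endowment.
fund_g_p1	funding	g	paraphrase	back		The authors did not receive any specific grant for this work from agencies in the public or commercial sectors.
fund_t1	funding	.	tricky	back	coi:c	S.S. has financial relationships with GSK.
reg_a_v1	registration	a	verbatim	methods		This study was registered on ClinicalTrials.gov (NCT12345678).
reg_b_v1	registration	b	verbatim	methods		This study was registered on PROSPERO (CRD42015023210).
reg_c_v1	registration	c	verbatim	methods		Our protocol was registered on the Chinese Clinical Trials Register (ChiCTR-IOR-12345678).
reg_d_v1	registration	d	verbatim	methods		Our research protocol is available on the ClinicalTrials.gov registry (NCT12345678).
reg_e_v1	registration	e	verbatim	methods		Trial registration: NCT12345678.
reg_f_v1	registration	f	verbatim	methods		Our study protocol was previously published (Serghiou et al. 2018).
reg_g_v1	registration	g	verbatim	back		Funded by the NIH. SPECS trial (NCT12345678).
reg_a_p1	registration	a	paraphrase	methods		Registration of this trial was completed prospectively on ClinicalTrials.gov (NCT87654321) before enrolment began.
reg_c_p1	registration	c	paraphrase	methods		We prospectively registered our study protocol with the regional clinical trials register.
reg_t1	registration	.	tricky	methods		This study enrolled patients in our hospital registry.
reg_t2	registration	.	tricky	methods		Our protocol was approved by the IRS (registration no. 123456).
data_a_v1	data_sharing	a	verbatim	availability		All data have been deposited on figshare and can be downloaded.
data_b_v1	data_sharing	b	verbatim	availability		Sequence data were deposited in dbSNP and can be downloaded.
data_c_v1	data_sharing	c	verbatim	availability		The datasets generated during this study were uploaded to GitHub.
data_e_v1	data_sharing	e	verbatim	availability		Raw measurements are archived as csv files in the online annex.
data_f_v1	data_sharing	f	verbatim	availability		The results supporting the conclusions are included as supplementary data files and are openly accessible.
data_g_v1	data_sharing	g	verbatim	availability		Data Availability Statement: the full set of measurements is openly deposited.
data_a_p1	data_sharing	a	paraphrase	availability		Deposited on Zenodo, the full dataset can be downloaded without restriction.
data_b_p1	data_sharing	b	paraphrase	availability		Newly generated sequences were submitted to GenBank and are accessible online.
data_t1	data_sharing	.	tricky	availability		Data are available from the corresponding author upon request.
data_t2	data_sharing	.	tricky	availability		Raw data were not deposited in any repository.
code_c_v1	code_sharing	c	verbatim	availability		All analysis scripts are available at GitHub.
code_d_v1	code_sharing	d	verbatim	availability		The python script used for the analysis can be downloaded from the project page.
code_c_p1	code_sharing	c	paraphrase	availability		Available at Bitbucket is the complete analysis pipeline used in this work.
code_d_p1	code_sharing	d	paraphrase	availability		Custom scripts supporting the analyses have been made openly available.
code_t1	code_sharing	.	tricky	availability		Code is available upon reasonable request.
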