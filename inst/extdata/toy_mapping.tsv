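code	item_id	kind	scale_value	label	chapter
I214	STEMI	main		ST-elevation myocardial infarction	CIR
I214	AMI_BROAD	main		Acute myocardial infarction (broad)	CIR
I219	AMI_BROAD	main		Acute myocardial infarction (broad)	CIR
A41	SEPSIS	main		Sepsis (broad)	INF
A4101	SEPSIS_MSSA	main		Sepsis due to MSSA	INF
A4101	SEPSIS	main		Sepsis (broad)	INF
Z6841	BMI	scale	41	Body mass index 40.0-44.9	FAC
Z6832	BMI	scale	32	Body mass index 32.0-32.9	FAC
V9733	INJ_EXT	modifier		External-cause modifier	cross-cutting
E6601	OBESITY	main		Obesity	END
E6601	SEV_COMPL	modifier		With complication	cross-cutting
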