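code	item_id	kind	scale_value	label	chapter
J9600	SEV1	main		Respiratory failure, unspecified	RSP
J9601	SEV2	main		Respiratory failure with hypoxia	RSP
J9602	SEV3	main		Respiratory failure with hypercapnia	RSP
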