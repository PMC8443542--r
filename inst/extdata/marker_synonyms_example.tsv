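Neotamias	Neotamias	Neotamias
CYTB	COI-5P	18SRIBOSOMALRNA
CYTOCHROMEB	CYTOCHROMEBOXIDASE	18SSMALLSUBUNITRIBOSOMALRNA
CYTOCHROME-B	CYTOCHROMECOXIDASESUBUNIT1
	CYTOCHROMECOXIDASESUBUNITI
	CYTOCHROMEOXIDASESUBUNIT1
	CYTOCHROMEOXIDASESUBUNITI
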