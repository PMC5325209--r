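proteome	emf	n_reference	n_identified
human	ELF	89796	26419
human	UMTS	89796	22957
human	WiFi	89796	24174
mouse	ELF	53213	13051
mouse	UMTS	53213	14106
mouse	WiFi	53213	13309
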