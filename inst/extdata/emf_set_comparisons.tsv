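proteome	set_a	set_b	set_c	n_a	n_b	n_c	n_intersect	n_union
human	ELF	UMTS	NA	26419	22957	NA	20711	28665
human	ELF	WiFi	NA	26419	24174	NA	21503	29090
human	UMTS	WiFi	NA	22957	24174	NA	20702	26429
mouse	ELF	UMTS	NA	13051	14106	NA	11365	15792
mouse	ELF	WiFi	NA	13051	13309	NA	11108	15252
mouse	UMTS	WiFi	NA	14106	13309	NA	12154	15261
human	ELF	UMTS	WiFi	26419	22957	24174	19389	30023
mouse	ELF	UMTS	WiFi	13051	14106	13309	10570	16409
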