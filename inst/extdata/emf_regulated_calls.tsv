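emf	cell_line	gene_symbol	direction
ELF	VH10	MLH1	up
ELF	VH10	UBE2A	up
ELF	VH10	WDR75	up
ELF	VH10	LEPREL2	up
ELF	VH10	NUMB	up
ELF	VH10	GINS1	up
ELF	U2OS	MVK	up
ELF	U2OS	TBL3	up
ELF	U2OS	DHX33	up
ELF	U2OS	AMPH	down
ELF	U2OS	DNMT1	down
ELF	U2OS	METAP2	down
ELF	U2OS	NT5C2	down
ELF	U2OS	LIMD1	down
ELF	IB10	Glmn	up
ELF	IB10	Rhot1	up
ELF	IB10	Cryzl1	up
ELF	IB10	Ap1m1	up
UMTS	VH10	SPAG7	up
UMTS	VH10	EXOC2	down
UMTS	VH10	DPY30	down
UMTS	VH10	KDM1A	down
UMTS	VH10	CRYZL1	down
UMTS	U2OS	MBOAT7	down
UMTS	U2OS	EXOC2	down
UMTS	U2OS	MOGS	down
UMTS	U2OS	H2AFY	down
UMTS	U2OS	PKP2	down
UMTS	U2OS	TWISTNB	down
UMTS	IB10	Calcoco1	up
UMTS	IB10	Pcf11	up
UMTS	IB10	Acbd6	down
UMTS	IB10	Wipi2	down
WiFi	VH10	ANKRD28	up
WiFi	VH10	LEO1	down
WiFi	VH10	PNPO	down
WiFi	VH10	KRAS	down
WiFi	U2OS	AKAP8L	down
WiFi	U2OS	NUCKS1	down
WiFi	IB10	Drosha	up
WiFi	IB10	Atxn7l3b	up
WiFi	IB10	Wwc2	up
WiFi	IB10	Nde1	up
WiFi	IB10	Asf1a	up
WiFi	IB10	Zfp57	down
WiFi	IB10	Scaf8	down
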