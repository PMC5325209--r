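emf	cell_line	n_identified	n_quant_rep1	n_quant_rep2	n_quant_complete	n_decoys	n_contaminants
ELF	U2OS	5286	3237	3288	2927	97	125
ELF	VH10	5286	3114	3305	2854	97	125
ELF	IB10	4583	3276	3389	3055	71	96
UMTS	U2OS	4551	3722	3656	3416	76	134
UMTS	VH10	4551	3233	3023	2761	76	134
UMTS	IB10	4933	4199	4035	3812	66	113
WiFi	U2OS	4841	3656	3803	3483	71	130
WiFi	VH10	4841	3294	3336	3028	71	130
WiFi	IB10	4662	4010	3958	3704	62	112
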