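! synthetic stand-in annotation table (GAF-like, pre-propagated); the
! protein-to-process edges are illustrative, not a curated export.
term	item	evidence
GO:0031061	H2AFY	IDA
GO:0031061	KDM1A	IMP
GO:0031061	DNMT1	IDA
GO:0006298	MLH1	IDA
GO:0006298	DNMT1	IGI
GO:0016571	KDM1A	IDA
GO:0016571	DPY30	TAS
GO:0016571	Asf1a	ISO
GO:0006325	H2AFY	IEA
GO:0006325	Drosha	NAS
GO:0006513	UBE2A	IDA
GO:0006513	LEO1	IEA
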