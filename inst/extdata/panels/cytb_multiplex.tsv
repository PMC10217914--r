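Name	Sequence	Tm	Amplicon_Length	Gene_Target	Targeted_Organism	Orientation
CytbUni_H15149	AAACTGCAGCCCCTCAGAATGATATTTGTCCTCA	71.01	NA	CYTB	Universal	R
CyMbF	GTAGGCGTTRTTCTTCTTCTG	59.41	106	CYTB	Mullus barbatus	F
CyPpF	TCGGCTCACTACTTGGGCTA	63.01	351	CYTB	Pseudupeneus prayensis	F
CyMsF	GCCTCTACTACGGCTCATAT	58.64	147	CYTB	Mullus surmuletus	F
CyUmF	TGCACTACACATCAGACATT	57.32	291	CYTB	Upeneus moluccensis	F
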