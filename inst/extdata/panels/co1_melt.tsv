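Name	Sequence	Tm	Amplicon_Length	Gene_Target	Targeted_Organism	Orientation
2COIUniF	AAGCCTYCTYATTCGTGC	60.18	NA	CO1	Universal	F
2COIUmR	TGGGATAAGTCAGTTACCAAAT	54.7	154	CO1	Upeneus moluccensis	R
2COIMbR	AACGCCTGAAGAGGCTAGTAGA	60.3	256	CO1	Mullus barbatus	R
2COIPpR	AAGAGAAAAAATAGTTAAGTCAACG	54.8	353	CO1	Pseudupeneus prayensis	R
2COIMsR	ATTGTGAAATTGCTGGAGGC	55.3	438	CO1	Mullus surmuletus	R
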