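Name	Sequence	Tm	Amplicon_Length	Gene_Target	Targeted_Organism	Orientation
COIUniF	AAGCCTYCTYATTCGTGC	60.18	NA	CO1	Universal	F
COIMbR	TTCGGGGGAAAGCCATATCG	62.54	193	CO1	Mullus barbatus	R
COIUmR	GGCAAGCAGTAGCAGGAAAGAA	63.62	244	CO1	Upeneus moluccensis	R
COIPpR	AAGAGAAAAAATAGTTAAGTCAACG	56.59	351	CO1	Pseudupeneus prayensis	R
COIMsR	ATTGTGAAATTGCTGGAGGC	59.58	436	CO1	Mullus surmuletus	R
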