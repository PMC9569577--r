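gene	category	note
ITGB1	1a	integrin
ITGB3	1a	integrin
GNAI2	1a	heterotrimeric G protein
TFRC	1a	transferrin receptor
HLA-A	1a	MHC class I
ITGA2B	1b	platelet
PECAM1	1b	endothelial
GYPA	1b	red blood cell
TSG101	2	ESCRT
ANXA5	2	membrane-binding
FLOT1	2	raft
FLOT2	2	raft
APOB	3	lipoprotein
ALB	3	serum albumin
APOA1	3	lipoprotein
APOA2	3	lipoprotein
HIST1H2AB	4	histone H2A
HIST1H4A	4	histone H4
HSP90B1	4	endoplasmin (ER)
CANX	4	calnexin (ER)
CALR	4	calreticulin (ER)
TGFB1	5	cytokine
VEGFA	5	growth factor
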