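accession	aspect	term
P11166	BP	cellular response to hypoxia
P11166	BP	glucose transmembrane transport
P04040	BP	response to oxidative stress
P04040	BP	hydrogen peroxide catabolic process
P27169	BP	response to oxidative stress
P02679	BP	blood coagulation, fibrin clot formation
P02671	BP	blood coagulation, fibrin clot formation
P02675	BP	blood coagulation, fibrin clot formation
P04275	BP	platelet aggregation
P04275	BP	blood coagulation
P07225	BP	blood coagulation
P16284-6	BP	vasculature development
P16284-6	CC	endothelial cell surface
P50552	BP	vascular endothelial cell migration
P63010-2	CC	clathrin-coated endocytic vesicle
P63010-2	CC	endosome membrane
P14625	CC	endoplasmic reticulum lumen
P27824-2	CC	endoplasmic reticulum membrane
P02786	BP	cellular iron ion homeostasis
P02786	CC	recycling endosome
P02787	BP	iron ion transport
P02790	BP	heme transport
P55072	BP	ubiquitin-dependent protein catabolic process
P55072	CC	transitional endoplasmic reticulum
O43866	BP	inflammatory response
P01871	BP	immune response
P01876	BP	immune response
P01834	BP	innate immune response
P02649	BP	amyloid-beta formation
P06276	MF	choline esterase activity
P26038	CC	secretory vesicle membrane
P27105	CC	secretory granule membrane
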