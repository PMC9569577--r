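accession	gene	protein_score	coverage_pct	peptides_95	log2_NAO_HC	sig_NAO_HC	log2_RVE_HC	sig_RVE_HC	log2_CD_HC	sig_CD_HC
Q13045	FLII	4.6	1.9	2	-0.58	FALSE	-2.11	TRUE	-2.86	TRUE
Q14204	DYNC1H1	6.9	0.4	2	-0.40	FALSE	-0.98	FALSE	-1.04	TRUE
P63010-2	AP2B1	7.1	2.7	3	-0.57	FALSE	-2.13	TRUE	-1.01	FALSE
P06276	BCHE	7.2	7.0	3	-0.12	FALSE	2.18	TRUE	2.39	TRUE
P62987	UBA52	7.4	29.7	3	-0.36	FALSE	-1.54	TRUE	-0.53	FALSE
Q15746-5	MYLK	8.0	2.2	4	-0.47	FALSE	-1.67	TRUE	-1.77	TRUE
P27824-2	CANX	8.3	8.0	4	-0.44	FALSE	-2.39	TRUE	-2.03	FALSE
H0YAC1	KLKB1	8.4	6.7	4	-0.58	FALSE	-0.50	FALSE	1.09	TRUE
O00139-4	KIF2A	8.4	6.5	4	-0.53	FALSE	-1.99	TRUE	-1.38	FALSE
P11166	SLC2A1	10.6	13.2	6	1.04	FALSE	-2.75	TRUE	-1.00	FALSE
A0A0G2JH68	DIAPH1	10.9	5.0	5	-0.33	FALSE	-2.10	TRUE	-1.74	TRUE
Q13576	IQGAP2	10.9	1.8	3	0.25	FALSE	-1.10	TRUE	-2.02	TRUE
P01833	PIGR	11.3	10.9	6	-0.88	FALSE	1.14	FALSE	1.70	TRUE
P16284-6	PECAM1	11.6	10.0	5	-0.45	FALSE	-1.21	TRUE	-1.61	TRUE
Q14697	GANAB	11.7	9.7	6	-0.53	FALSE	-1.25	TRUE	-1.50	TRUE
P07225	PROS1	11.9	10.8	6	-0.13	FALSE	1.16	TRUE	1.24	TRUE
A0A0A0MRD9	HPR	12.3	55.5	39	-2.50	FALSE	1.04	FALSE	2.50	TRUE
P14625	HSP90B1	13.4	9.2	6	-0.68	FALSE	-2.68	TRUE	-1.59	TRUE
P35611-3	ADD1	13.4	9.8	6	0.39	FALSE	-1.85	TRUE	0.00	FALSE
E7EMK3	FLOT2	14.2	18.0	7	-0.35	FALSE	-1.54	TRUE	-0.62	FALSE
P02749	APOH	14.5	28.1	12	-0.27	FALSE	-2.76	TRUE	-1.75	TRUE
P50552	VASP	15.0	19.7	7	-0.64	FALSE	-3.36	TRUE	-1.42	TRUE
P04004	VTN	17.5	20.9	13	-0.23	FALSE	-1.82	TRUE	-0.78	FALSE
P04040	CAT	17.6	22.8	8	0.61	TRUE	-0.23	FALSE	0.16	FALSE
P25705	ATP5A1	18.3	21.2	9	-0.31	FALSE	-1.81	TRUE	-1.90	TRUE
P20742	PZP	18.6	16.8	126	-1.04	FALSE	0.01	FALSE	1.53	TRUE
Q9Y6R7	FCGBP	19.0	3.1	9	-1.37	TRUE	1.37	TRUE	2.48	TRUE
P02790	HPX	19.3	21.9	10	0.82	TRUE	-0.90	TRUE	0.11	FALSE
P02786	TFRC	19.5	14.2	9	-1.77	TRUE	-0.27	FALSE	0.01	FALSE
P27169	PON1	20.0	39.7	11	0.82	TRUE	-0.39	FALSE	-0.29	FALSE
P01042-2	KNG1	23.1	28.6	12	0.69	TRUE	-1.02	TRUE	0.24	FALSE
O14791	APOL1	25.3	34.7	14	-1.33	TRUE	0.25	FALSE	1.91	TRUE
O43866	CD5L	25.6	41.2	16	-0.69	TRUE	0.74	TRUE	1.99	TRUE
P27105	STOM	27.0	50.0	20	-0.07	FALSE	-0.82	TRUE	-1.34	TRUE
P40197	GP5	27.7	33.6	17	-0.45	FALSE	-2.15	TRUE	-1.90	TRUE
P04003	C4BPA	28.1	28.3	19	-0.23	FALSE	1.22	TRUE	1.42	TRUE
P16452	EPB42	29.5	19.0	16	0.96	TRUE	-1.53	TRUE	-0.72	FALSE
P26038	MSN	29.6	28.4	17	-0.17	FALSE	-1.73	TRUE	-0.44	FALSE
P05106	ITGB3	32.8	22.8	21	-0.56	FALSE	-2.26	TRUE	-2.13	TRUE
Q08380	LGALS3BP	35.9	34.4	23	-1.12	TRUE	1.10	TRUE	2.03	TRUE
P02647	APOA1	39.2	56.9	23	-0.80	FALSE	-1.40	TRUE	0.96	TRUE
P11171-2	EPB41	39.8	30.6	21	0.98	TRUE	-2.48	TRUE	-0.60	FALSE
P02649	APOE	40.1	68.4	25	0.13	FALSE	-0.72	FALSE	-0.94	TRUE
P55072	VCP	43.9	36.6	21	-0.61	TRUE	0.09	FALSE	0.08	FALSE
P01009	SERPINA1	45.2	55.5	32	0.33	FALSE	-1.47	TRUE	-0.09	FALSE
P08519	LPA	46.5	29.2	38	1.36	TRUE	0.05	FALSE	-0.48	FALSE
A0A0A0MRJ7	F5	47.3	11.9	22	-0.29	FALSE	-2.13	TRUE	-1.29	TRUE
O75636	FCN3	48.3	64.9	87	0.27	FALSE	-1.00	TRUE	-0.93	TRUE
P04275	VWF	48.7	9.7	28	-0.43	FALSE	-1.09	TRUE	1.49	TRUE
P01876	IGHA1	52.9	56.9	68	-0.85	FALSE	-0.07	FALSE	1.16	TRUE
P01834	IGKC	54.5	91.6	123	-0.28	FALSE	0.40	FALSE	1.94	TRUE
P02679	FGG	69.2	61.6	99	-0.49	FALSE	-2.56	TRUE	0.43	FALSE
P00738	HP	73.8	64.5	92	0.29	FALSE	2.33	TRUE	2.22	TRUE
P02787	TF	75.2	52.6	57	0.58	TRUE	-1.95	TRUE	0.07	FALSE
P02730	SLC4A1	98.1	41.8	99	1.05	TRUE	-3.16	TRUE	-1.05	TRUE
P02751-15	FN1	101.6	27.5	67	-0.85	TRUE	0.76	TRUE	1.54	TRUE
P02671	FGA	105.5	42.8	152	-0.19	FALSE	-3.56	TRUE	0.33	FALSE
P02675	FGB	110.1	81.9	118	-0.48	FALSE	-3.48	TRUE	0.28	FALSE
P16157-14	ANK1	145.5	45.4	110	0.94	TRUE	-2.25	TRUE	-0.41	FALSE
P01871	IGHM	192.7	69.1	390	-4.07	TRUE	1.30	TRUE	2.62	TRUE
P11277-2	SPTB	200.6	50.1	129	0.80	TRUE	-3.20	TRUE	-0.53	FALSE
P02549	SPTA1	230.4	57.0	138	0.73	TRUE	-2.96	TRUE	-0.36	TRUE
P02768	ALB	258.4	85.5	399	1.21	TRUE	-2.75	TRUE	0.05	FALSE
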