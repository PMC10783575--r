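accession	gene	site	sequence_13	log2_effect	p_joint
E9Q616	Ahnak	S2000	GELKGPSVDVEVP	-0.39	0.0001
A1IGU4	Arhgef37	S15	ASSKSESPEQEDQ	-0.38	0.0003
O88379	Baz1a	S1412	RGRKRQSTESSPV	-0.42	0.0001
Q9D219	Bcl9	S104	KRERSISADSFDQ	-0.33	0.0001
Q6EDY6	Carmil1	S1328	SSPRSFSQEASRR	-0.31	0.0001
Q9JLQ0	Cd2ap	S233	LRTRTSSSETEEK	-0.52	0.0000
Q04899	Cdk18	S66	QNQRRFSMEDLNK	-0.33	0.0005
Q09XV5	Chd8	S2040	ARSRLTSQDYEVR	-0.41	0.0005
Q8CJ61	Cmtm4	S194	IRARTESRDVDSR	-0.53	0.0000
Q80XI3	Eif4g3	S1151	TFLRGSSKDLLDN	-0.69	0.0000
Q05D44	Eif5b	S108	QKGKKTSFDENDS	-0.43	0.0000
P18608	Hmgn1	S7	MPKRKVSADGAAK	-0.52	0.0000
Q6ZPV2	Ino80	S470	HQARTRSFDEDAK	-0.43	0.0000
P15066	Jund	S100	GLLKLASPELERL	-0.68	0.0000
Q5SVQ0	Kat7	S228	CKVRAQSRDKQIE	-0.46	0.0001
B1AVY7	Kif16b	S838	QLVKLASLEKDLV	-0.47	0.0003
P57016	Lad1	T19	SLARQRTLEDEEE	-0.79	0.0000
Q3UH68	Limch1	S379	SRRRSASQDLIKK	-0.58	0.0000
Q9Z2D1	Mtmr2	S6	_MEKSSSCESLGA	-0.33	0.0004
Q5HZI1	Mtus1	S1143	AISRQLSTEQAAL	-0.45	0.0001
Q78HU3	Mvb12a	S168	QDMRGLSLDPPKE	-0.74	0.0000
Q9CX66	Nopchap1	S125	EMSRSDSKEEDSP	-0.46	0.0002
Q9DBS9	Osbpl3	S33	QGSRQDSWEVVEG	-0.40	0.0000
Q62048	Pea15	S116	DIIRQPSEEEIIK	-0.78	0.0000
Q9DBC7	Prkar1a	S77	TGIRTDSREDEIS	-0.36	0.0003
Q6GYP7	Ralgapa1	T753	SIVRQKTVDIDDA	-0.39	0.0002
Q8BU14	Sec62	S309	KQQKSDSEEKSDS	-0.40	0.0003
Q9CY58	Serbp1	S329	VLHKSKSEEAHAE	-0.94	0.0000
Q6ZWQ0	Syne2	T6489	LLLRQGTDDSKEG	-0.65	0.0000
Q8CC35	Synpo	S258	HLEKVASEEEEVP	-0.54	0.0000
P39447	Tjp1	S1051	YIEKQASRDLEQP	-0.63	0.0000
Q9Z0U1	Tjp2	S988	SQNREDSFDYSKS	-1.10	0.0000
P20065	Tmsb4x	T29	KLKKTETQEKNPL	-0.64	0.0000
Q99PP7	Trim33	S1134	RRKRLKSDERPVH	-0.37	0.0003
Q8BJ05	Zc3h14	S309	VKVKRFSHDGEEE	-0.38	0.0004
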