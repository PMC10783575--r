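accession	gene	site	sequence_13	log2_effect	p_joint
Q9Z277	Baz1b	S325	KKPKRDSSSLSSP	-0.124	0.0002
P11440	Cdk1	T14	EKIGEGTYGVVYK	0.525	0.0000
P11440	Cdk1	Y15	KIGEGTYGVVYKG	0.461	0.0000
Q04899	Cdk18	S66	QNQRRFSMEDLNK	-0.332	0.0005
O08796	Eef2k	S444	GDSGYPSEKRSDL	-1.136	0.0000
P70424	Erbb2	Y878	DIDETEYHADGGK	-0.190	0.0001
Q9ESL4	Map3k20	S567	PGSRSDSSADCQW	0.371	0.0002
Q9ESL4	Map3k20	S638	NPSRSSSPTQYGL	0.432	0.0000
Q8BPM2	Map4k5	S433	QVLRRQSSPSCVP	-0.450	0.0000
Q3U214	Mast3	S702	RYRHLGSEDDETN	0.434	0.0001
Q6P9R2	Oxsr1	S359	AISQLRSPRVKDS	0.450	0.0000
Q8CIN4	Pak2	T143	QKYLSFTPPEKDG	-0.462	0.0004
Q8CEE6	Pask	S852	ILHRQTSDILVDR	0.519	0.0000
Q5EG47	Prkaa1	S508	SCQRSDSDAEAQG	-0.306	0.0004
Q5EG47	Prkaa1	T490	AKSGTATPQRSGS	0.366	0.0000
P97313	Prkdc	S3215	VDEDEESIDREVY	0.291	0.0001
O54988	Slk	S779	KDSGSVSLQETRR	0.511	0.0000
O55098	Stk10	S13	RRILRLSTFEKRK	0.469	0.0001
Q9WTK7	Stk11	S31	FIHRIDSTEVIYQ	-0.275	0.0004
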