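accession	gene	site	sequence_13	log2_effect	p_joint
Q9DBR7	Ppp1r12a	S445	GLRKTGSYGALAE	0.305	0.0000
Q9DBR7	Ppp1r12a	T669	RRRSYLTPVRDEE	0.318	0.0002
Q9DCL8	Ppp1r2	S90	EDAYSDSEGNEVM	-0.446	0.0001
Q76I79	Ssh1	T981	GSLNFSTEDLSSE	0.305	0.0004
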