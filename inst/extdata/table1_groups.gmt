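group1_unique_SCLC	published marker table group 1	RB1	E2F1	E2F2	CCNT2	CMYC	CEBPA	TP53	CDKN2A	HDAC4
group2_common_SCLC_NSCLC	published marker table group 2	RB1	E2F1	E2F2	CCNT2	CMYC	CEBPA	TP53	CDKN2A	HDAC4
group3_common_all	published marker table group 3	RB1	E2F1	E2F2	CCNT2	CMYC	CEBPA	TP53	CDKN2A	HDAC4
group4_common_NSCLC_general	published marker table group 4	TFDP2	AHR	CCND1	TP73	RBL2	TAF1	PML	BCL6	MYB	WT1	PARP1	PCAF	TWIST	MCM7
group5_NSCLC_specific	published marker table group 5	E2F6	TFDP1	SUV39H1	HNRPD
group6_general_specific	published marker table group 6	RBL1	IRF1	HMGA1
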