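step	pool	name	sequence
RT	RT_primer	HG_RT-in	AGAGGTGCTCTTGGAG
RT	RT_primer	Cmu_RT-in	GGGAATTCTCACAGGAG
RT	RT_primer	Kappa_RT-in	CACACAACAGAGGCAG
RT	RT_primer	Lambda_RT-in	CACCAGTGTGGCCTTG
RT	TSO	TSO	AAGCAGTGGTATCAACGCAGAGTACATGGG
PCR1	TSO_PCR	TSO-PCR_primer	AAGCAGTGGTATCAACGCAG
PCR1	BCR_PCR1	unb_HG_IN_new	AGAGGTGCTCTTGGAG
PCR1	BCR_PCR1	unb_Cmu_OUT	GGGAATTCTCACAGGAG
PCR1	BCR_PCR1	unb_Kappa_OUT	CACACAACAGAGGCAGTTCC
PCR1	BCR_PCR1	unb_Lambda_OUT	CACCAGTGTGGCCTTGTTGG
PCR2	Nextera_TSO	Nextera_NN_TSO-2ndPCR	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAGNNCAGTGGTATCAACGCAGAG
PCR2	Nextera_TSO	Nextera_NNN_TSO-2ndPCR	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAGNNNCAGTGGTATCAACGCAGAG
PCR2	Nextera_TSO	Nextera_NNNN_TSO-2ndPCR	TCGTCGGCAGCGTCAGATGTGTATAAGAGACAGNNNNCAGTGGTATCAACGCAGAG
PCR2	Nextera_BCR	Nextera_NN_IGHJ	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNGAGGAGACGGTGACCRKGGT
PCR2	Nextera_BCR	Nextera_NNN_IGHJ	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNNGAGGAGACGGTGACCRKGGT
PCR2	Nextera_BCR	Nextera_NNNN_IGHJ	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNNNGAGGAGACGGTGACCRKGGT
PCR2	Nextera_BCR	Nextera_NN_Kappa	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNGAAGATGAAGACAGATGGTGC
PCR2	Nextera_BCR	Nextera_NNN_Kappa	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNNGAAGATGAAGACAGATGGTGC
PCR2	Nextera_BCR	Nextera_NNNN_Kappa	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNNNGAAGATGAAGACAGATGGTGC
PCR2	Nextera_BCR	Nextera_NN_Lambda	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNGCTTGGAGCTCCTCAGAGG
PCR2	Nextera_BCR	Nextera_NNN_Lambda	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNNGCTTGGAGCTCCTCAGAGG
PCR2	Nextera_BCR	Nextera_NNNN_Lambda	GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAGNNNNGCTTGGAGCTCCTCAGAGG
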