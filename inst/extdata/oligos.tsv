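# Oligonucleotides (5'->3'). role: lri = long range-inverse PCR,
# mpx1/mpx2 = multiplex long-range PCR panels for PBX1 breakpoint clusters 1
# and 2, qpcr = generic breakpoint qPCR (TCF3-FAM is the dual-labeled
# 6FAM/BHQ1 hybridization probe; label column gives the dye/quencher).
name	sequence	role	label
TCF3-R4	GAAGGCCTGGGCTACGGAGGGGAACAGCT	lri	.
TCF3-F2	CTCCCTGACCTGTCTCGGCCTCCCGACT	lri	.
TCF3-F6	ACCTTGATTCTATCACTCCTAGGCCAGGGCA	lri	.
TCF3-R5	CACAGGCCTCCATTCATGTCCCTTCCGCA	lri	.
TaqI-R	AGGCCGTGGAGACCCCCGTCGTAGCT	lri	.
TCF3-F7	AGGAGGGTTTCAGGCAGAGGGCGCA	mpx1	.
PBX-long1	CCCGGGGTTGTGCTTCCTCCACCCTT	mpx1	.
PBX-long2	TGCGCTCTCTCCCTCCCCCTCATCTCT	mpx1	.
PBX-long3	ACGTGGTCCTGCGAGGAGCTCTTAGA	mpx1	.
PBX-long4	TGCCCATGCAGCAGGTGACAAGGG	mpx1	.
PBX1-long5	ACGAATCAGGCAGCTGTACAGAAAGCA	mpx2	.
PBX1-long6	TCGGCCTCACCTAACTGACTTGCAGGT	mpx2	.
PBX1-long7	AGCACCATCCTGAAGTTGCTCGGCT	mpx2	.
PBX1-long8	TGCGGGAGGCTGGCAACATTGAGTC	mpx2	.
PBX1-long9	ACACAGGTGCTACCTCTGCTCTGCCA	mpx2	.
PBX1-long10	TCCAGCTACCTCATGGCTCGCTAGA	mpx2	.
TCF3-qF	CAGGCAGACTTTCCAAGTACCTT	qpcr	.
TCF3-FAM	CTATCACTCCTAGGCCAGGGCATCT	qpcr	6FAM/BHQ1
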