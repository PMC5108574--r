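region	haplotype	control	autism	printed_p	printed_or
centromeric	cA01	6248	110	0.00001	0.53
centromeric	cB01	1184	41	0.0045	1.69
centromeric	cB02	1566	27	0.1576	0.73
centromeric	cB03	26	0	1	NA
telomeric	tA01	6968	130	0.00004	0.53
telomeric	tB01	2055	48	0.7347	1.06
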