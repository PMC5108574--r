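haplotype	agre	control	printed_p	printed_or
cA01/tA01	84	5133	0.06	0.74
cA01/tB01	23	1114	0.638	1.11
cB01/tB01	13	461	0.157	1.538
cB02/tA01	17	1112	0.41	0.791
cB01/tA01	25	697	0.002	2.06
cB02/tB01	8	480	0.863	0.879
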