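category	inherited	noninherited	printed_pct_inherited	printed_pct_noninherited	printed_p	printed_or
C1k/C1k	25	13	59.5	33.3	0.026	2.941
C1k/C2k	15	20	35.7	51.3	0.183	0.528
C2k/C2k	2	6	4.8	15.4	0.146	0.275
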