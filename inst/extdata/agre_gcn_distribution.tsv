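gene	present	absent	gcn0	gcn1	gcn2	gcn3	printed_total	printed_ratio
2DS2	56	33	33	51	5	0	61	1.09
2DL2	53	36	36	50	3	0	56	1.06
2DL3	77	12	12	45	32	0	109	1.42
2DL5c	27	62	62	25	2	0	29	1.07
2DS35c	27	62	62	25	2	0	29	1.07
2DP1	88	1	1	29	59	0	147	1.67
2DL1	88	1	1	26	62	0	150	1.70
3DP1	89	0	0	4	78	7	181	2.03
2DL4	89	0	0	4	78	7	181	2.03
3DL1	85	4	4	39	45	1	132	1.55
3DS1	42	47	47	35	7	0	49	1.17
2DL5t	44	45	45	40	4	0	48	1.09
2DS35t	44	45	45	40	4	0	48	1.09
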