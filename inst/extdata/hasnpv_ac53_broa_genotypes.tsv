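genotype	bitmask	reads
BRO-A_G_33554431	33554431	258084
BRO-A_G_33554303	33554303	1643
BRO-A_G_33552383	33552383	787
BRO-A_G_16777215	16777215	666
BRO-A_G_33554423	33554423	533
BRO-A_G_25165823	25165823	437
BRO-A_G_33554430	33554430	437
BRO-A_G_33292287	33292287	400
BRO-A_G_31457279	31457279	393
BRO-A_G_33554429	33554429	261
BRO-A_G_33554399	33554399	228
BRO-A_G_33554427	33554427	213
BRO-A_G_33553919	33553919	138
BRO-A_G_33554175	33554175	129
BRO-A_G_33546239	33546239	123
BRO-A_G_33554367	33554367	105
BRO-A_G_29360127	29360127	103
BRO-A_G_33030143	33030143	103
BRO-A_G_33550335	33550335	92
BRO-A_G_33552255	33552255	68
BRO-A_G_33521663	33521663	62
BRO-A_G_33554415	33554415	56
BRO-A_G_33554428	33554428	55
BRO-A_G_20971519	20971519	52
BRO-A_G_33553407	33553407	48
BRO-A_G_23068671	23068671	35
BRO-A_G_33554239	33554239	28
BRO-A_G_33538047	33538047	21
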