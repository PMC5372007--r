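genotype	bitmask	reads
BRO-A_G_1	1	104065
BRO-A_G_0	0	87689
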