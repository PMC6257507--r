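snp_a	snp_b	r2
rs1800562	rs198846	0.45
rs1800562	rs129128	0.12
rs1799945	rs198846	0.05
rs855791	rs2413450	0.95
rs9990333	rs3811647	0.28
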