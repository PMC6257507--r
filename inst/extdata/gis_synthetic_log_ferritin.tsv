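snp	effect_allele	other_allele	beta	se	pvalue	eaf	n
rs1800562	A	G	0.204	0.017	4.0e-33	0.07	48972
rs1799945	G	C	0.065	0.011	7.0e-9	0.15	48972
rs855791	A	G	-0.055	0.008	1.1e-11	0.56	48972
rs9990333	T	C	0.010	0.008	2.2e-1	0.46	48972
rs7385804	A	C	0.022	0.008	4.3e-3	0.62	48972
rs411988	A	G	0.043	0.007	1.1e-9	0.47	48972
rs8177240	T	G	0.012	0.008	1.3e-1	0.67	48972
rs174577	A	C	0.045	0.0075	2.1e-9	0.34	48972
rs651007	T	C	-0.022	0.008	6.0e-3	0.20	48972
rs6486121	T	C	0.011	0.007	1.2e-1	0.36	48972
rs236918	C	G	0.045	0.0075	2.0e-9	0.12	48972
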