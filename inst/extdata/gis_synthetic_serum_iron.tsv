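snp	effect_allele	other_allele	beta	se	pvalue	eaf	n
rs1800562	A	G	0.328	0.016	2.7e-94	0.07	48972
rs1799945	G	C	0.189	0.011	1.1e-63	0.15	48972
rs855791	A	G	-0.181	0.008	1.4e-110	0.56	48972
rs9990333	T	C	0.050	0.008	2.0e-9	0.46	48972
rs7385804	A	C	0.064	0.009	1.0e-12	0.62	48972
rs411988	A	G	0.015	0.007	3.2e-2	0.47	48972
rs8177240	T	G	-0.010	0.008	2.1e-1	0.67	48972
rs174577	A	C	0.020	0.008	1.2e-2	0.34	48972
rs651007	T	C	0.044	0.008	1.0e-8	0.20	48972
rs6486121	T	C	0.010	0.007	1.5e-1	0.36	48972
rs236918	C	G	0.030	0.009	8.0e-4	0.12	48972
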