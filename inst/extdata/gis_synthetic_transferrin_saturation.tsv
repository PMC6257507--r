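snp	effect_allele	other_allele	beta	se	pvalue	eaf	n
rs1800562	A	G	0.577	0.016	1.0e-270	0.07	48972
rs1799945	G	C	0.231	0.011	1.9e-95	0.15	48972
rs855791	A	G	-0.190	0.008	4.8e-123	0.56	48972
rs9990333	T	C	0.048	0.009	1.1e-7	0.46	48972
rs7385804	A	C	0.049	0.009	6.0e-8	0.62	48972
rs411988	A	G	0.020	0.008	1.2e-2	0.47	48972
rs8177240	T	G	0.018	0.008	2.4e-2	0.67	48972
rs174577	A	C	0.019	0.008	1.7e-2	0.34	48972
rs651007	T	C	0.030	0.008	1.8e-4	0.20	48972
rs6486121	T	C	0.012	0.007	9.0e-2	0.36	48972
rs236918	C	G	0.031	0.008	1.1e-4	0.12	48972
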