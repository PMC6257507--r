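snp	effect_allele	other_allele	beta	se	pvalue	eaf	n
rs1800562	A	G	-0.479	0.017	4.0e-171	0.07	48972
rs1799945	G	C	-0.114	0.012	1.3e-21	0.15	48972
rs855791	G	A	-0.046	0.008	1.0e-8	0.44	48972
rs9990333	T	C	-0.021	0.008	9.0e-3	0.46	48972
rs7385804	A	C	-0.019	0.008	1.9e-2	0.62	48972
rs411988	A	G	-0.011	0.007	1.2e-1	0.47	48972
rs8177240	T	G	-0.380	0.008	1.0e-300	0.67	48972
rs174577	A	C	0.022	0.008	6.0e-3	0.34	48972
rs651007	T	C	-0.015	0.008	6.1e-2	0.20	48972
rs6486121	T	C	0.039	0.007	2.5e-8	0.36	48972
rs236918	C	G	0.012	0.008	1.3e-1	0.12	48972
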