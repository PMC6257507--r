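snp	phenotype	pvalue
rs1799945	systolic_blood_pressure	1.0e-10
rs1799945	diastolic_blood_pressure	3.0e-9
rs1800562	ldl_cholesterol	2.0e-15
rs1800562	total_cholesterol	1.0e-12
rs855791	mean_corpuscular_hemoglobin	5.0e-30
rs855791	glycated_hemoglobin	1.0e-7
rs7385804	red_blood_cell_count	4.0e-12
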